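# Independent oracles used to freeze expected values.  These deliberately
# re-derive results by brute force and must not call the code paths they
# check.

# Dice over padded character n-grams, enumerated longhand.
oracle_ngram <- function(w1, w2, n = 3L) {
  grams <- function(w) {
    s <- paste0(strrep("#", n - 1L), w, strrep("#", n - 1L))
    sapply(seq_len(nchar(s) - n + 1L), function(i) substr(s, i, i + n - 1L))
  }
  g1 <- grams(w1); g2 <- grams(w2)
  shared <- 0L
  g2pool <- g2
  for (g in g1) {
    hit <- match(g, g2pool)
    if (!is.na(hit)) { shared <- shared + 1L; g2pool <- g2pool[-hit] }
  }
  2 * shared / (length(g1) + length(g2))
}

# Exhaustive maximum one-to-one matching over element pairs whose word
# similarity is strictly above the threshold (recursion over all pairings;
# only feasible for tiny profiles).
oracle_intersection <- function(t1, t2, syn, params = ccoem_params()) {
  ok <- outer(seq_along(t1), seq_along(t2), Vectorize(function(i, j)
    word_similarity(t1[i], t2[j], syn, params) >
      params$element_match_threshold))
  recurse <- function(i, used2) {
    if (i > length(t1)) return(0L)
    best <- recurse(i + 1L, used2)
    for (j in seq_along(t2)) {
      if (ok[i, j] && !used2[j]) {
        used2[j] <- TRUE
        best <- max(best, 1L + recurse(i + 1L, used2))
        used2[j] <- FALSE
      }
    }
    best
  }
  recurse(1L, logical(length(t2)))
}

# Global MatchFmeasure optimum by enumerating every mapping vector and
# every useful threshold (feasible for n1, n2 <= 4).
oracle_best_fmeasure <- function(sim) {
  n1 <- nrow(sim); n2 <- ncol(sim)
  thresholds <- sort(unique(c(0, sim[sim > 0])))
  best <- 0
  maps <- as.matrix(expand.grid(rep(list(0:n2), n1)))
  for (k in seq_len(nrow(maps))) {
    m <- maps[k, ]
    i <- which(m > 0)
    if (!length(i)) next
    s <- sim[cbind(i, m[i])]
    for (t in thresholds) {
      keep <- s >= t & s > 0
      nc <- sum(keep)
      if (!nc) next
      nt <- length(unique(m[i][keep]))
      ratio <- (nc + nt) / (2 * nc)
      coverage <- (nc + nt) / (n1 + n2)
      best <- max(best, 2 * coverage * ratio / (coverage + ratio))
    }
  }
  best
}

# Hand-built three-concept ontology: B and C are direct subclasses of A.
tiny_ontology <- function(ns = "http://example.org/t#",
                          labels = c(A = "Alpha Organ", B = "Beta Tissue",
                                     C = "Gamma Cell")) {
  new_ontology(ns, list(
    new_concept(paste0(ns, "A"), labels = labels[["A"]],
                children = paste0(ns, c("B", "C"))),
    new_concept(paste0(ns, "B"), labels = labels[["B"]]),
    new_concept(paste0(ns, "C"), labels = labels[["C"]])))
}

extdata <- function(f) system.file("extdata", f, package = "ccoem")
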