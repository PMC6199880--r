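#' Synonym provider backed by a flat term-pair table
#'
#' Stand-in for a biomedical metathesaurus lookup (e.g. UMLS synonymy):
#' a symmetric, reflexive relation over normalized single words, loaded
#' wholesale from a two-column tab-separated file or a two-column data
#' frame.  Pairs are stored both ways in a hashed environment so lookups
#' are O(1).
#'
#' @param source path to a TSV file (two columns, one pair per line, no
#'   header), a two-column data frame, or `NULL` for an empty provider.
#' @return an object of class `ccoem_synonyms`.
#' @export
synonym_provider <- function(source = NULL) {
  env <- new.env(parent = emptyenv(), hash = TRUE)
  add_pair <- function(a, b) {
    a <- normalize_term(a); b <- normalize_term(b)
    if (length(a) != 1L || length(b) != 1L) return(invisible())
    assign(paste(a, b, sep = "\r"), TRUE, envir = env)
    assign(paste(b, a, sep = "\r"), TRUE, envir = env)
  }
  if (is.character(source) && length(source) == 1L) {
    if (!file.exists(source)) stop("synonym file not found: ", source)
    if (file.size(source) == 0 ||
        !length(readLines(source, n = 1L, warn = FALSE)))
      return(structure(list(table = env), class = "ccoem_synonyms"))
    tab <- utils::read.table(source, sep = "\t", header = FALSE,
                             quote = "", comment.char = "",
                             stringsAsFactors = FALSE, colClasses = "character")
    source <- tab
  }
  if (is.data.frame(source)) {
    stopifnot(ncol(source) >= 2L)
    for (i in seq_len(nrow(source))) add_pair(source[[1L]][i], source[[2L]][i])
  } else if (!is.null(source)) {
    stop("source must be a file path, a data frame, or NULL")
  }
  structure(list(table = env), class = "ccoem_synonyms")
}

#' Query a synonym provider
#'
#' Reflexive (`is_synonym(s, a, a)` is always `TRUE`) and symmetric by
#' construction of the stored table.
#'
#' @param syn a [synonym_provider()].
#' @param w1,w2 normalized words (vectors recycle elementwise).
#' @return logical vector.
#' @export
is_synonym <- function(syn, w1, w2) {
  n <- max(length(w1), length(w2))
  w1 <- rep_len(w1, n); w2 <- rep_len(w2, n)
  same <- w1 == w2
  keys <- paste(w1, w2, sep = "\r")
  hit <- vapply(keys, exists, logical(1), envir = syn$table,
                inherits = FALSE, USE.NAMES = FALSE)
  same | hit
}

#' @export
print.ccoem_synonyms <- function(x, ...) {
  cat("<ccoem_synonyms> ", length(ls(x$table)) / 2, " pairs\n", sep = "")
  invisible(x)
}

padded_ngrams <- function(w, n) {
  if (n == 1L) return(strsplit(w, "", fixed = TRUE)[[1L]])
  pad <- strrep("#", n - 1L)
  s <- paste0(pad, w, pad)
  k <- nchar(s) - n + 1L
  substring(s, seq_len(k), seq_len(k) + n - 1L)
}

multiset_intersection_size <- function(a, b) {
  ta <- table(a); tb <- table(b)
  common <- intersect(names(ta), names(tb))
  if (!length(common)) return(0L)
  sum(pmin(as.integer(ta[common]), as.integer(tb[common])))
}

#' Padded n-gram string similarity (Dice)
#'
#' Frames each word with `n - 1` boundary markers, extracts its character
#' n-grams and scores the pair with the Dice coefficient
#' `2 |g1 ∩ g2| / (|g1| + |g2|)` over gram multisets.  Identical words
#' score 1; words sharing no gram score 0; the measure is symmetric.
#'
#' @param w1,w2 single words (already normalized).
#' @param n gram order, default 3 (trigrams).
#' @return a number in `[0, 1]`.
#' @examples
#' ngram_similarity("myocardium", "myocardium")  # 1
#' ngram_similarity("abc", "xyz")                # 0
#' @export
ngram_similarity <- function(w1, w2, n = 3L) {
  stopifnot(n >= 1L)
  if (identical(w1, w2)) return(1)
  g1 <- padded_ngrams(w1, n); g2 <- padded_ngrams(w2, n)
  shared <- multiset_intersection_size(g1, g2)
  if (shared == 0L) return(0)
  2 * shared / (length(g1) + length(g2))
}

#' Word-level similarity: synonymy first, then n-grams
#'
#' 1 when the two words are synonymous under the provider, otherwise the
#' padded n-gram similarity.
#'
#' @param w1,w2 normalized words.
#' @param syn a [synonym_provider()].
#' @param params a [ccoem_params()] (uses `ngram_size`).
#' @return a number in `[0, 1]`.
#' @export
word_similarity <- function(w1, w2, syn, params = ccoem_params()) {
  if (is_synonym(syn, w1, w2)) return(1)
  ngram_similarity(w1, w2, params$ngram_size)
}

# Pairwise word-similarity matrix over two vocabularies, used as a cache
# so the evolutionary loop never re-tokenizes or re-scores strings.
word_similarity_matrix <- function(words1, words2, syn,
                                   params = ccoem_params()) {
  n <- params$ngram_size
  g1 <- lapply(words1, padded_ngrams, n = n)
  g2 <- lapply(words2, padded_ngrams, n = n)
  m <- matrix(0, length(words1), length(words2),
              dimnames = list(words1, words2))
  for (i in seq_along(words1)) {
    for (j in seq_along(words2)) {
      if (words1[i] == words2[j]) { m[i, j] <- 1; next }
      shared <- multiset_intersection_size(g1[[i]], g2[[j]])
      if (shared > 0L)
        m[i, j] <- 2 * shared / (length(g1[[i]]) + length(g2[[j]]))
    }
  }
  # synonym overrides
  for (i in seq_along(words1)) {
    hit <- is_synonym(syn, words1[i], words2)
    m[i, hit] <- 1
  }
  m
}

greedy_intersection_from_matrix <- function(wm, threshold) {
  cand <- which(wm > threshold, arr.ind = TRUE)
  if (!nrow(cand)) return(0L)
  vals <- wm[cand]
  ord <- order(-vals, cand[, 1L], cand[, 2L])
  used1 <- logical(nrow(wm)); used2 <- logical(ncol(wm))
  count <- 0L
  for (k in ord) {
    i <- cand[k, 1L]; j <- cand[k, 2L]
    if (!used1[i] && !used2[j]) {
      used1[i] <- TRUE; used2[j] <- TRUE
      count <- count + 1L
    }
  }
  count
}

#' Size of the semantic intersection of two profiles
#'
#' Counts profile elements identified as identical: pairs whose word
#' similarity is strictly above `element_match_threshold`, matched
#' greedily one-to-one in descending similarity order (ties broken by
#' element position).  Never exceeds `min(|p1|, |p2|)`.
#'
#' @param p1,p2 `ccoem_profile`s (or bare character vectors of terms).
#' @param syn a [synonym_provider()].
#' @param params a [ccoem_params()].
#' @return a non-negative integer.
#' @export
profile_intersection_size <- function(p1, p2, syn, params = ccoem_params()) {
  t1 <- if (is.character(p1)) p1 else p1$terms
  t2 <- if (is.character(p2)) p2 else p2$terms
  if (!length(t1) || !length(t2)) return(0L)
  wm <- word_similarity_matrix(t1, t2, syn, params)
  greedy_intersection_from_matrix(wm, params$element_match_threshold)
}

#' Delta-gated profile similarity
#'
#' The two asymmetric measures `s1 = I / |p1|` and `s2 = I / |p2|` (with
#' `I` the semantic intersection size) are averaged when they agree to
#' within `delta`, and the pair scores 0 otherwise:
#' `sim = (s1 + s2) / 2` if `|s1 - s2| <= delta`, else `0`.  The result
#' is symmetric in its two arguments.
#'
#' @inheritParams profile_intersection_size
#' @return a number in `[0, 1]`.
#' @export
profile_similarity <- function(p1, p2, syn, params = ccoem_params()) {
  t1 <- if (is.character(p1)) p1 else p1$terms
  t2 <- if (is.character(p2)) p2 else p2$terms
  if (!length(t1) || !length(t2))
    stop("profile similarity is undefined for an empty profile")
  I <- profile_intersection_size(t1, t2, syn, params)
  s1 <- I / length(t1); s2 <- I / length(t2)
  if (abs(s1 - s2) <= params$delta) (s1 + s2) / 2 else 0
}

#' Pairwise concept-similarity matrix of two ontologies
#'
#' Computes `profile_similarity` for every source/target concept pair.
#' Word-level similarities are computed once over the joint vocabularies
#' and cached, so the cost is one string comparison per vocabulary pair
#' rather than per concept pair.
#'
#' @param o1,o2 `ccoem_ontology` objects.
#' @param syn a [synonym_provider()].
#' @param params a [ccoem_params()].
#' @param profiles1,profiles2 optional precomputed [build_profiles()]
#'   results.
#' @return an `n1 x n2` numeric matrix of class `ccoem_simmatrix` with
#'   source IRIs as row names and target IRIs as column names; absent
#'   (zero) entries mean no similarity.
#' @export
similarity_matrix <- function(o1, o2, syn, params = ccoem_params(),
                              profiles1 = NULL, profiles2 = NULL) {
  if (is.null(profiles1)) profiles1 <- build_profiles(o1)
  if (is.null(profiles2)) profiles2 <- build_profiles(o2)
  vocab1 <- sort(unique(unlist(lapply(profiles1, `[[`, "terms"))))
  vocab2 <- sort(unique(unlist(lapply(profiles2, `[[`, "terms"))))
  wm <- word_similarity_matrix(vocab1, vocab2, syn, params)
  idx1 <- lapply(profiles1, function(p) match(p$terms, vocab1))
  idx2 <- lapply(profiles2, function(p) match(p$terms, vocab2))
  n1 <- length(profiles1); n2 <- length(profiles2)
  m <- matrix(0, n1, n2,
              dimnames = list(names(profiles1), names(profiles2)))
  thr <- params$element_match_threshold
  for (i in seq_len(n1)) {
    li <- length(idx1[[i]])
    sub_i <- wm[idx1[[i]], , drop = FALSE]
    if (all(sub_i <= thr)) next
    for (j in seq_len(n2)) {
      sub <- sub_i[, idx2[[j]], drop = FALSE]
      I <- greedy_intersection_from_matrix(sub, thr)
      if (I == 0L) next
      s1 <- I / li; s2 <- I / length(idx2[[j]])
      if (abs(s1 - s2) <= params$delta) m[i, j] <- (s1 + s2) / 2
    }
  }
  class(m) <- c("ccoem_simmatrix", class(m))
  m
}
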