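CONSONANTS <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r",
                "s", "t", "v", "z")
VOWELS <- c("a", "e", "i", "o", "u")

# pronounceable pseudo-words (CV syllables) so that n-gram similarity
# behaves like it does on real vocabulary instead of on random noise
make_pseudo_words <- function(k, n_syllables = 3L, taken = character()) {
  out <- character(0)
  guard <- 0L
  while (length(out) < k) {
    guard <- guard + 1L
    if (guard > 10000L + 100L * k)
      stop("pseudo-word pool exhausted")
    w <- paste(paste0(sample(CONSONANTS, n_syllables, replace = TRUE),
                      sample(VOWELS, n_syllables, replace = TRUE)),
               collapse = "")
    if (w %in% taken || w %in% out) next
    out <- c(out, w)
  }
  out
}

corrupt_word <- function(w) {
  pos <- sample.int(nchar(w), 1L)
  cur <- substr(w, pos, pos)
  repl <- sample(setdiff(letters, cur), 1L)
  paste0(substr(w, 1L, pos - 1L), repl,
         substr(w, pos + 1L, nchar(w)))
}

#' Generate an ontology pair with known ground truth
#'
#' Builds a random single-parent (tree-shaped) source ontology whose
#' concepts carry multi-word labels of unique pronounceable pseudo-words,
#' then derives the target ontology from a copy by (i) renaming one label
#' word of a fraction of concepts through generated synonym pairs, (ii)
#' corrupting one character of one label word of another fraction, and
#' (iii) dropping a fraction of (non-root) concepts, re-attaching their
#' children to the grandparent.  The surviving identity mapping is the
#' one-to-one ground-truth alignment; the synonym pairs used are returned
#' as the emulated synonym dictionary.
#'
#' @param n_concepts number of source concepts (>= 1).
#' @param branching_factor arity of the complete tree (default 3).
#' @param synonym_rename_fraction,char_noise_fraction,dropout_fraction
#'   perturbation fractions in `[0, 1]`.
#' @param words_per_label words per concept label (default 2).
#' @param seed optional integer seed.
#' @return a list of class `ccoem_fixture` with `o1`, `o2`
#'   (`ccoem_ontology`), `reference` (`ccoem_alignment`), `synonyms`
#'   (a [synonym_provider()]) and `synonym_table` (data frame).
#' @export
generate_pair <- function(n_concepts, branching_factor = 3L,
                          synonym_rename_fraction = 0,
                          char_noise_fraction = 0,
                          dropout_fraction = 0,
                          words_per_label = 2L, seed = NULL) {
  stopifnot(n_concepts >= 1, branching_factor >= 1,
            synonym_rename_fraction >= 0, synonym_rename_fraction <= 1,
            char_noise_fraction >= 0, char_noise_fraction <= 1,
            dropout_fraction >= 0, dropout_fraction <= 1,
            words_per_label >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_concepts)
  words <- matrix(make_pseudo_words(n * words_per_label),
                  nrow = n, ncol = words_per_label)
  labels1 <- apply(words, 1L, paste, collapse = " ")
  iri1 <- sprintf("http://example.org/src#C%04d", seq_len(n))
  iri2 <- sprintf("http://example.org/tgt#D%04d", seq_len(n))
  parent <- c(NA_integer_,
              if (n > 1L) (seq(2L, n) - 2L) %/% branching_factor + 1L)
  children_of <- function(iris) {
    kids <- vector("list", n)
    for (i in seq_len(n)[-1L])
      kids[[parent[i]]] <- c(kids[[parent[i]]], iris[i])
    kids
  }
  kids1 <- children_of(iri1)
  o1 <- new_ontology("source", lapply(seq_len(n), function(i)
    new_concept(iri1[i], labels = labels1[i], children = kids1[[i]])))

  # --- perturb a copy into the target ontology ---
  words2 <- words
  syn_from <- character(0); syn_to <- character(0)
  n_ren <- round(synonym_rename_fraction * n)
  if (n_ren > 0L) {
    ren <- sample.int(n, n_ren)
    repl <- make_pseudo_words(n_ren, taken = as.vector(words))
    for (k in seq_along(ren)) {
      col <- sample.int(words_per_label, 1L)
      syn_from <- c(syn_from, words2[ren[k], col])
      syn_to <- c(syn_to, repl[k])
      words2[ren[k], col] <- repl[k]
    }
  }
  n_noise <- round(char_noise_fraction * n)
  if (n_noise > 0L) {
    noisy <- sample.int(n, n_noise)
    for (i in noisy) {
      col <- sample.int(words_per_label, 1L)
      words2[i, col] <- corrupt_word(words2[i, col])
    }
  }
  labels2 <- apply(words2, 1L, paste, collapse = " ")

  keep <- rep(TRUE, n)
  n_drop <- round(dropout_fraction * n)
  if (n_drop > 0L) {
    droppable <- seq_len(n)[-1L]
    keep[sample(droppable, min(n_drop, length(droppable)))] <- FALSE
  }
  # re-attach children of dropped concepts to the nearest kept ancestor
  eff_parent <- parent
  for (i in seq_len(n)[-1L]) {
    p <- parent[i]
    while (!is.na(p) && !keep[p]) p <- parent[p]
    eff_parent[i] <- p
  }
  kids2 <- vector("list", n)
  for (i in seq_len(n)[-1L]) {
    if (!keep[i]) next
    p <- eff_parent[i]
    if (!is.na(p)) kids2[[p]] <- c(kids2[[p]], iri2[i])
  }
  surv <- which(keep)
  o2 <- new_ontology("target", lapply(surv, function(i)
    new_concept(iri2[i], labels = labels2[i], children = kids2[[i]])))

  reference <- new_alignment(iri1[surv], iri2[surv], rep(1, length(surv)))
  synonym_table <- data.frame(term1 = syn_from, term2 = syn_to,
                              stringsAsFactors = FALSE)
  structure(list(o1 = o1, o2 = o2, reference = reference,
                 synonyms = synonym_provider(
                   if (nrow(synonym_table)) synonym_table else NULL),
                 synonym_table = synonym_table),
            class = "ccoem_fixture")
}

#' Write a fixture to disk
#'
#' Emits the two ontologies as OWL RDF/XML, the ground-truth alignment in
#' both the OAEI Alignment RDF format and TSV, and the synonym table as
#' TSV.
#'
#' @param pair a [generate_pair()] result.
#' @param directory output directory (created if missing).
#' @return named character vector of the written paths.
#' @export
write_fixture <- function(pair, directory) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  paths <- c(
    o1 = file.path(directory, "source.owl"),
    o2 = file.path(directory, "target.owl"),
    reference_rdf = file.path(directory, "reference.rdf"),
    reference_tsv = file.path(directory, "reference.tsv"),
    synonyms = file.path(directory, "synonyms.tsv"))
  write_ontology(pair$o1, paths[["o1"]])
  write_ontology(pair$o2, paths[["o2"]])
  write_alignment(pair$reference, paths[["reference_rdf"]], "rdf")
  write_alignment(pair$reference, paths[["reference_tsv"]], "tsv")
  utils::write.table(pair$synonym_table, paths[["synonyms"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  paths
}
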