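#' Matcher parameters
#'
#' Collects every tunable constant of the similarity measure and of the
#' compact coevolutionary search in one list, with the defaults used
#' throughout the package.
#'
#' @param delta gate width for the asymmetric profile-similarity
#'   combination rule.  Two profiles score `(s1 + s2) / 2` only when
#'   `|s1 - s2| <= delta`, and 0 otherwise.  Suggested domain
#'   `[0.01, 0.10]`; 0.06 performs well on biomedical vocabularies.
#' @param element_match_threshold word-level similarity above which two
#'   profile elements count as identical when sizing the profile
#'   intersection.  Strictly-greater comparison; default 0.9 keeps
#'   "identical" strict.
#' @param ngram_size character n-gram order for the string similarity
#'   (default 3, i.e. trigrams).
#' @param num_accuracy numerical accuracy of the decoded alignment
#'   threshold; the threshold gene can represent any multiple of this
#'   value in `[0, 1]`.  Default 0.01.
#' @param update_rate per-generation step by which every probability-vector
#'   element moves toward the elite's bit value.  Default 0.1.
#' @param crossover_probability continuation probability `pc` of the
#'   local-search crossover: the copied fragment grows by one position
#'   while successive uniform draws stay below `pc`.  Default 0.6.
#' @param mutation_probability per-bit flip probability applied to each
#'   freshly sampled candidate.  Default 0.03.
#' @param mutation_rate magnitude of the occasional probability-vector
#'   perturbation toward 0.5 (applied per element with probability
#'   `mutation_probability` each generation); set 0 to disable.
#'   Default 0.05.
#' @param max_generation number of generations of the evolutionary loop.
#'   Default 3000.
#' @param exchange_first if `TRUE`, swarms exchange elites before (rather
#'   than after) their own generation step.  Default `FALSE`
#'   (update-then-help).
#'
#' @return a list of class `ccoem_params`.
#' @examples
#' p <- ccoem_params(max_generation = 500)
#' p$delta
#' @export
ccoem_params <- function(delta = 0.06,
                         element_match_threshold = 0.9,
                         ngram_size = 3L,
                         num_accuracy = 0.01,
                         update_rate = 0.1,
                         crossover_probability = 0.6,
                         mutation_probability = 0.03,
                         mutation_rate = 0.05,
                         max_generation = 3000L,
                         exchange_first = FALSE) {
  stopifnot(delta >= 0, delta <= 1,
            element_match_threshold >= 0, element_match_threshold <= 1,
            ngram_size >= 1,
            num_accuracy > 0, num_accuracy <= 1,
            update_rate > 0, update_rate < 1,
            crossover_probability > 0, crossover_probability < 1,
            mutation_probability >= 0, mutation_probability <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            max_generation >= 0)
  structure(list(
    delta = delta,
    element_match_threshold = element_match_threshold,
    ngram_size = as.integer(ngram_size),
    num_accuracy = num_accuracy,
    update_rate = update_rate,
    crossover_probability = crossover_probability,
    mutation_probability = mutation_probability,
    mutation_rate = mutation_rate,
    max_generation = as.integer(max_generation),
    exchange_first = isTRUE(exchange_first)
  ), class = "ccoem_params")
}
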