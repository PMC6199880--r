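# Fast fitness evaluators.  The evolutionary loop evaluates thousands of
# candidate chromosomes against one fixed similarity matrix, so the
# decode -> filter -> count path is fully vectorized and never builds the
# correspondence data frame (that only happens once, for the final
# returned alignment).
make_objective <- function(tag = c("matchFmeasure", "matchRatio",
                                   "matchCoverage"),
                           sim, enc) {
  tag <- match.arg(tag)
  n1 <- nrow(sim); n2 <- ncol(sim)
  force(sim); force(enc)
  function(bits) {
    sol <- decode_chromosome(bits, enc)
    i <- which(sol$mapping > 0L)
    if (!length(i)) return(0)
    j <- sol$mapping[i]
    s <- sim[cbind(i, j)]
    keep <- s >= sol$threshold & s > 0
    ncorr <- sum(keep)
    if (!ncorr) return(0)
    ns <- ncorr                       # sources are distinct by encoding
    nt <- length(unique(j[keep]))
    ratio <- (ns + nt) / (2 * ncorr)
    if (tag == "matchRatio") return(ratio)
    coverage <- (ns + nt) / (n1 + n2)
    if (tag == "matchCoverage") return(coverage)
    match_fmeasure(coverage, ratio)
  }
}

#' Local-search crossover (circular fragment copy)
#'
#' Builds a neighbor of the elite by overwriting `L` consecutive
#' positions (counted circularly from a uniformly drawn cut point) with
#' the corresponding genes of a freshly sampled candidate.  The fragment
#' grows by one position while successive uniform draws stay below `pc`
#' (a geometric law truncated at the chromosome length), so with
#' `pc = 0.6` the expected fragment is short and the operator is strongly
#' exploitative: the neighbor differs from the elite only where the
#' fragment happens to cover a differing gene.
#'
#' @param ind_new candidate 0/1 vector (fragment donor).
#' @param ind_elite elite 0/1 vector (recipient).
#' @param pc fragment continuation probability in `(0, 1)`.
#' @param cut,fragment_length fixed cut point / fragment length, mainly
#'   for worked examples and tests; both drawn randomly when `NULL`.
#' @return the neighbor 0/1 vector.
#' @export
local_search_crossover <- function(ind_new, ind_elite, pc,
                                   cut = NULL, fragment_length = NULL) {
  len <- length(ind_elite)
  if (length(ind_new) != len)
    stop("chromosome lengths differ in crossover")
  stopifnot(pc > 0, pc < 1)
  if (is.null(cut)) cut <- sample.int(len, 1L)
  if (is.null(fragment_length)) {
    fragment_length <- 1L
    while (fragment_length < len && stats::runif(1) < pc)
      fragment_length <- fragment_length + 1L
  }
  pos <- ((cut - 1L + seq_len(fragment_length) - 1L) %% len) + 1L
  ind_elite[pos] <- ind_new[pos]
  ind_elite
}

new_swarm <- function(pv, objective_fn, draws = NULL) {
  elite <- if (is.null(draws)) sample_chromosome(pv)
           else sample_chromosome(pv, draws)
  list(pv = pv, elite = elite,
       elite_fitness = objective_fn(elite), generation = 0L)
}

# occasional drift of PV elements toward 0.5, keeping residual diversity
perturb_pv <- function(pv, pm, magnitude) {
  if (magnitude <= 0 || pm <= 0) return(pv)
  sel <- stats::runif(length(pv)) < pm
  if (!any(sel)) return(pv)
  step <- 0.5 - pv[sel]
  pv[sel] <- pv[sel] + pmax(pmin(step, magnitude), -magnitude)
  pv
}

#' One generation of the compact EA
#'
#' Samples a candidate from the probability vector, mutates it, derives a
#' neighbor of the elite via [local_search_crossover()], keeps the best
#' of candidate / neighbor / elite (the incumbent elite wins ties), and
#' applies the per-element perturbation toward 0.5.  The probability
#' vector moves toward the elite only in generations that produced a
#' *new* elite: updating it unconditionally would saturate every element
#' at 0 or 1 within a few dozen generations and leave the sampler unable
#' to explore (empirically worse than uniform random search on toy
#' instances), whereas the update-on-improvement reading lets the
#' perturbation re-diversify the vector while the search is stuck.
#'
#' @param state swarm state: list with `pv`, `elite`, `elite_fitness`,
#'   `generation`.
#' @param objective_fn function mapping a 0/1 chromosome to a fitness in
#'   `[0, 1]`.
#' @param params a [ccoem_params()].
#' @param samples number of candidate/neighbor pairs drawn this
#'   generation (default 1; used to grant a single swarm the evaluation
#'   budget of several).
#' @return the updated swarm state.
#' @export
cea_generation <- function(state, objective_fn, params = ccoem_params(),
                           samples = 1L) {
  improved <- FALSE
  for (k in seq_len(samples)) {
    candidate <- mutate_chromosome(sample_chromosome(state$pv),
                                   params$mutation_probability)
    neighbor <- local_search_crossover(candidate, state$elite,
                                       params$crossover_probability)
    fc <- objective_fn(candidate)
    fn <- objective_fn(neighbor)
    best_f <- max(fc, fn)
    if (best_f > state$elite_fitness) {
      state$elite <- if (fn >= fc) neighbor else candidate
      state$elite_fitness <- best_f
      improved <- TRUE
    }
  }
  if (improved)
    state$pv <- update_pv(state$pv, state$elite, params$update_rate)
  state$pv <- perturb_pv(state$pv, params$mutation_probability,
                         params$mutation_rate)
  state$generation <- state$generation + 1L
  state
}

#' Run a single-swarm compact EA
#'
#' Initializes the probability vector uniformly at 0.5, draws the initial
#' elite from it, and iterates [cea_generation()] for `max_generation`
#' generations.  Only the elite, the current candidate/neighbor pair and
#' the probability vector are ever held in memory — there is no
#' population array.
#'
#' @param sim a [similarity_matrix()].
#' @param objective one of `"matchFmeasure"`, `"matchRatio"`,
#'   `"matchCoverage"`.
#' @param params a [ccoem_params()].
#' @param seed optional integer seed (set once at entry).
#' @param num_accuracy threshold grid step (defaults to
#'   `params$num_accuracy`).
#' @param max_generation overrides `params$max_generation` when given.
#' @param samples_per_generation candidate/neighbor pairs per generation
#'   (see [cea_generation()]).
#' @return a list of class `ccoem_swarm` with the final `pv`, `elite`,
#'   `elite_fitness`, `generation`, the encoding and a per-generation
#'   `trace` of the elite fitness.
#' @export
run_cea <- function(sim, objective = "matchFmeasure",
                    params = ccoem_params(), seed = NULL,
                    num_accuracy = params$num_accuracy,
                    max_generation = params$max_generation,
                    samples_per_generation = 1L) {
  if (!is.null(seed)) set.seed(seed)
  enc <- encoding_params(nrow(sim), ncol(sim), num_accuracy)
  obj <- make_objective(objective, sim, enc)
  state <- new_swarm(rep(0.5, enc$length), obj)
  trace <- numeric(max_generation)
  g <- 0L
  while (g < max_generation) {
    state <- cea_generation(state, obj, params, samples_per_generation)
    g <- g + 1L
    trace[g] <- state$elite_fitness
  }
  structure(c(state, list(enc = enc, objective = objective, trace = trace)),
            class = "ccoem_swarm")
}
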