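OBJECTIVE_TAGS <- c(mr = "matchRatio", mc = "matchCoverage",
                    mf = "matchFmeasure")

#' Elite migration between the three subswarms
#'
#' Every swarm's current elite is scored under every other swarm's
#' objective (a fixed 3 x 3 table computed from the pre-exchange elites).
#' Scanning the swarms in the fixed order ratio, coverage, f-measure,
#' each swarm adopts the best foreign elite that *strictly* beats its
#' incumbent under its own objective, and moves its probability vector
#' toward the adopted chromosome.  Ties keep the incumbent, so the
#' exchange never lowers any swarm's elite fitness.
#'
#' @param swarms named list (`mr`, `mc`, `mf`) of swarm states.
#' @param objectives named list of the three objective functions.
#' @param params a [ccoem_params()].
#' @return the updated swarm list.
#' @export
exchange_elites <- function(swarms, objectives, params = ccoem_params()) {
  tags <- names(OBJECTIVE_TAGS)
  fit <- matrix(NA_real_, 3L, 3L, dimnames = list(tags, tags))
  for (s in tags) {
    for (o in tags) {
      fit[s, o] <- if (s == o) swarms[[s]]$elite_fitness
                   else objectives[[o]](swarms[[s]]$elite)
    }
  }
  elites <- lapply(swarms, `[[`, "elite")
  for (o in tags) {
    foreign <- setdiff(tags, o)
    best <- foreign[which.max(fit[foreign, o])]
    if (fit[best, o] > swarms[[o]]$elite_fitness) {
      swarms[[o]]$elite <- elites[[best]]
      swarms[[o]]$elite_fitness <- fit[best, o]
      swarms[[o]]$pv <- update_pv(swarms[[o]]$pv, elites[[best]],
                                  params$update_rate)
    }
  }
  swarms
}

#' Match two ontologies with the compact coevolutionary algorithm
#'
#' Builds the concept profiles and the similarity matrix once, then
#' evolves three probability-vector subswarms — maximizing MatchRatio,
#' MatchCoverage and MatchFmeasure respectively — for `max_generation`
#' generations.  Each generation every swarm performs one
#' [cea_generation()] step and the swarms then exchange elites via
#' [exchange_elites()], so that the precision and recall surrogates
#' improve jointly instead of one at the other's expense.  The final
#' alignment is decoded from the f-measure swarm's elite.
#'
#' @param o1,o2 source and target `ccoem_ontology` objects.
#' @param syn a [synonym_provider()] (empty provider if `NULL`).
#' @param params a [ccoem_params()].
#' @param seed optional integer seed controlling the whole run.
#' @param sim optional precomputed [similarity_matrix()] (avoids
#'   recomputing it across repeated runs on the same pair).
#' @param max_generation overrides `params$max_generation` when given.
#' @param trace_file optional path: per-generation elite fitness triples
#'   are appended as CSV.
#' @return a list of class `ccoem_result` with `alignment` (a
#'   `ccoem_alignment`), `swarms` (final states), `trace` (generations x
#'   3 matrix of elite fitnesses), `enc` and `params`.
#' @export
run_ccea <- function(o1, o2, syn = NULL, params = ccoem_params(),
                     seed = NULL, sim = NULL,
                     max_generation = params$max_generation,
                     trace_file = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(syn)) syn <- synonym_provider()
  if (is.null(sim)) sim <- similarity_matrix(o1, o2, syn, params)
  enc <- encoding_params(nrow(sim), ncol(sim), params$num_accuracy)
  objectives <- lapply(OBJECTIVE_TAGS, make_objective, sim = sim, enc = enc)
  swarms <- lapply(objectives, function(obj)
    new_swarm(rep(0.5, enc$length), obj))
  trace <- matrix(NA_real_, max_generation, 3L,
                  dimnames = list(NULL, names(OBJECTIVE_TAGS)))
  for (g in seq_len(max_generation)) {
    if (params$exchange_first)
      swarms <- exchange_elites(swarms, objectives, params)
    for (s in names(swarms))
      swarms[[s]] <- cea_generation(swarms[[s]], objectives[[s]], params)
    if (!params$exchange_first)
      swarms <- exchange_elites(swarms, objectives, params)
    trace[g, ] <- vapply(swarms, `[[`, numeric(1), "elite_fitness")
  }
  if (!is.null(trace_file))
    utils::write.csv(data.frame(generation = seq_len(nrow(trace)), trace),
                     trace_file, row.names = FALSE)
  sol <- decode_chromosome(swarms$mf$elite, enc)
  alignment <- decode_to_alignment(sol, sim, o1, o2)
  structure(list(alignment = alignment, swarms = swarms, trace = trace,
                 enc = enc, params = params, threshold = sol$threshold),
            class = "ccoem_result")
}

#' @export
print.ccoem_result <- function(x, ...) {
  f <- if (nrow(x$trace)) x$trace[nrow(x$trace), "mf"] else NA_real_
  cat("<ccoem_result> ", nrow(x$alignment), " correspondences",
      "; decoded threshold ", format(x$threshold),
      "; final MatchFmeasure ", format(round(f, 4)), "\n", sep = "")
  invisible(x)
}
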