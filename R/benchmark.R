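# Degradation benchmark harness: random biomass generation, class-stratified
# reaction removal, completion and recovery evaluation.

#' Random biomass reaction by Bernoulli zeroing
#'
#' Returns a copy of a base biomass reaction in which each reactant
#' coefficient is independently removed with probability `zero_prob`
#' (Bernoulli-distributed binary choices). If every reactant would be
#' removed, the draw is repeated, so at least one reactant is always
#' retained. Deterministic given `rng_seed`.
#'
#' @param net A `gs_network` containing the base biomass.
#' @param base_biomass Reaction id of the biomass to randomize.
#' @param zero_prob Probability in `[0, 1)` of zeroing each reactant.
#' @param rng_seed Integer seed.
#' @param new_id Id for the returned reaction (default: keep the base id).
#' @return A `gs_reaction`.
#' @export
random_biomass <- function(net, base_biomass, zero_prob, rng_seed,
                           new_id = base_biomass) {
  stopifnot(inherits(net, "gs_network"),
            zero_prob >= 0, zero_prob < 1)
  base <- net$reactions[[base_biomass]]
  if (is.null(base)) stop("biomass reaction '", base_biomass, "' not found",
                          call. = FALSE)
  if (!length(base$reactants)) {
    stop("biomass reaction '", base_biomass, "' has no reactants",
         call. = FALSE)
  }
  with_local_seed(rng_seed, {
    repeat {
      keep <- stats::runif(length(base$reactants)) >= zero_prob
      if (any(keep)) break
    }
    reaction(new_id, base$reactants[keep], base$products,
             reversible = base$reversible, name = base$name)
  })
}

# Per-class removal counts: round half away from zero, then adjust the
# largest class by +/-1 steps until the global count is exact.
stratified_counts <- function(n_per_class, fraction) {
  target_total <- round(fraction * sum(n_per_class))
  counts <- floor(fraction * n_per_class + 0.5)
  counts <- pmin(counts, n_per_class)
  diff <- target_total - sum(counts)
  while (diff != 0) {
    if (diff > 0) {
      room <- which(counts < n_per_class)
      i <- room[which.max(n_per_class[room])]
      counts[i] <- counts[i] + 1L
      diff <- diff - 1L
    } else {
      pos <- which(counts > 0)
      i <- pos[which.max(n_per_class[pos])]
      counts[i] <- counts[i] - 1L
      diff <- diff + 1L
    }
  }
  counts
}

#' Class-stratified random degradation of a network
#'
#' Removes the same fraction of essential, alternative and blocked reactions
#' (per the supplied classification), sampling uniformly without replacement
#' within each class. The biomass reaction itself is never removed. With
#' `require_nonfunctional = TRUE` the draw is repeated (up to `max_retries`)
#' until the degraded network cannot produce the biomass by FBA.
#' Deterministic given `rng_seed`.
#'
#' @param net Reference `gs_network` (must contain `biomass_id`).
#' @param fraction Removal fraction in (0, 1).
#' @param classes Named character vector from [classify_reactions()]
#'   covering the removable reactions of `net`.
#' @param rng_seed Integer seed.
#' @param require_nonfunctional Resample until FBA optimum of the degraded
#'   model is below tolerance.
#' @param biomass_id Biomass reaction id (kept; used for the FBA check).
#' @param seeds Seed metabolite ids for the FBA check.
#' @param max_retries Retry bound for the non-functionality requirement.
#' @param tol Functionality tolerance on the FBA optimum.
#' @return An object of class `gs_degradation`: `reference`, `degraded`,
#'   `removed`, `per_class_removed`, `rng_seed`, `fraction`.
#' @export
degrade <- function(net, fraction, classes, rng_seed,
                    require_nonfunctional = FALSE, biomass_id,
                    seeds = character(), max_retries = 100, tol = 1e-6) {
  stopifnot(inherits(net, "gs_network"), fraction > 0, fraction < 1)
  classes <- classes[setdiff(names(classes), biomass_id)]
  missing <- setdiff(setdiff(reaction_ids(net), biomass_id), names(classes))
  if (length(missing)) {
    stop("classes must cover the network reactions; missing: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  lvls <- c("essential", "alternative", "blocked")
  by_class <- lapply(lvls, function(cl) sort(names(classes)[classes == cl]))
  names(by_class) <- lvls
  counts <- stratified_counts(lengths(by_class), fraction)

  with_local_seed(rng_seed, {
    for (attempt in seq_len(max_retries)) {
      removed <- unlist(lapply(lvls, function(cl) {
        pool <- by_class[[cl]]
        k <- counts[[cl]]
        if (k == 0L) character() else pool[sample.int(length(pool), k)]
      }), use.names = FALSE)
      keep <- setdiff(reaction_ids(net), removed)
      degraded <- met_network(unname(net$reactions[keep]), net$metabolites)
      ok <- TRUE
      if (require_nonfunctional) {
        opt <- fba_max(build_flux_model(degraded, seeds, biomass_id))
        ok <- opt$objective <= tol
      }
      if (ok) {
        per_class <- vapply(lvls, function(cl) {
          sum(removed %in% by_class[[cl]])
        }, integer(1))
        return(structure(list(reference = net, degraded = degraded,
                              removed = sort(removed),
                              per_class_removed = per_class,
                              rng_seed = rng_seed, fraction = fraction),
                         class = "gs_degradation"))
      }
    }
    stop("could not reach a non-functional degradation in ", max_retries,
         " attempts", call. = FALSE)
  })
}

#' @export
print.gs_degradation <- function(x, ...) {
  cat(sprintf("<degradation: fraction %.2f, removed %d reactions (%s)>\n",
              x$fraction, length(x$removed),
              paste(names(x$per_class_removed), x$per_class_removed,
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Evaluate a filled network against a degradation record
#'
#' Measures how well gap-filling recovered what degradation destroyed:
#' whether the filled network is FBA-functional, how many removed
#' reference-essential reactions reappear in it, the 3x3 classification
#' drift matrix (reference class vs post-fill class, over reactions present
#' in the filled network, when both models are functional), and the outcome
#' category: `"functional"` (biomass restored), `"all_essential"` (not
#' functional but every removed essential recovered), `"missed_one"`,
#' `"missed_several"`.
#'
#' @param record A `gs_degradation`.
#' @param filled `gs_network`: the degraded network plus the reactions added
#'   by gap-filling (must be a superset of the degraded network and contain
#'   `biomass_id`).
#' @param biomass_id Objective reaction id.
#' @param seeds Seed metabolite ids for the flux models.
#' @param reference_classes Optional precomputed [classify_reactions()]
#'   labels of the reference model (avoids recomputation across
#'   experiments).
#' @param delta,tol Classification parameters, as in [classify_reactions()].
#' @return List of class `gs_evaluation`: `functional_after`,
#'   `essential_recovered` (count), `essential_removed` (count),
#'   `recovery_fraction`, `missed_essential`, `category`, `class_drift`
#'   (matrix or `NULL`), `solution_size`.
#' @export
evaluate_completion <- function(record, filled, biomass_id,
                                seeds = character(),
                                reference_classes = NULL,
                                delta = 1, tol = 1e-6) {
  stopifnot(inherits(record, "gs_degradation"), inherits(filled, "gs_network"))
  if (!biomass_id %in% reaction_ids(filled)) {
    stop("biomass reaction '", biomass_id, "' absent from filled network",
         call. = FALSE)
  }
  missing <- setdiff(reaction_ids(record$degraded), reaction_ids(filled))
  if (length(missing)) {
    stop("filled network must contain the degraded network; missing: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  if (is.null(reference_classes)) {
    reference_classes <- classify_reactions(
      build_flux_model(record$reference, seeds, biomass_id), delta, tol)
  }
  removed_essential <- intersect(
    record$removed, names(reference_classes)[reference_classes == "essential"])
  recovered <- intersect(removed_essential, reaction_ids(filled))
  missed <- length(removed_essential) - length(recovered)

  filled_model <- build_flux_model(filled, seeds, biomass_id)
  functional_after <- fba_max(filled_model)$objective > tol

  category <- if (functional_after) "functional"
    else if (missed == 0L) "all_essential"
    else if (missed == 1L) "missed_one"
    else "missed_several"

  drift <- NULL
  if (functional_after) {
    filled_classes <- classify_reactions(filled_model, delta, tol)
    common <- intersect(names(reference_classes), names(filled_classes))
    lvls <- c("essential", "alternative", "blocked")
    drift <- table(factor(reference_classes[common], levels = lvls),
                   factor(filled_classes[common], levels = lvls),
                   dnn = c("reference", "filled"))
    drift <- unclass(drift)
  }
  structure(list(
    functional_after = functional_after,
    essential_recovered = length(recovered),
    essential_removed = length(removed_essential),
    recovery_fraction = if (length(removed_essential))
      length(recovered) / length(removed_essential) else 1,
    missed_essential = missed,
    category = category,
    class_drift = drift,
    solution_size = length(setdiff(reaction_ids(filled),
                                   reaction_ids(record$degraded)))),
    class = "gs_evaluation")
}

#' Run the degradation benchmark at configurable scale
#'
#' One full pass of the benchmark design on a reference model: draw a random
#' biomass, classify the reference reactions against it, degrade the network
#' class-stratified at each fraction, gap-fill each degraded network from
#' the reference (using the union of all minimal completions, the tool's
#' output), and evaluate recovery. The default scale is a desk-size smoke
#' preset; genome-scale grids (many networks, many biomasses) are larger
#' presets of the same function, not a different code path.
#'
#' @param model List with `network`, `seeds`, `biomass_id`
#'   (e.g. [benchmark_model()]).
#' @param fractions Removal fractions (default `c(0.1, 0.2, 0.3, 0.4)`).
#' @param rng_seeds Integer vector: one degradation per (fraction, seed).
#' @param biomass_zero_prob Zeroing probability for the random biomass
#'   (default 0.25).
#' @param biomass_seed Seed for the random biomass draw (default first of
#'   `rng_seeds`).
#' @param require_nonfunctional Passed to [degrade()].
#' @param delta,tol Classification parameters.
#' @return Data frame with one row per experiment: `fraction`, `rng_seed`,
#'   `n_removed`, `removed_essential`, `removed_alternative`,
#'   `removed_blocked`, `optimum_size`, `solution_size`, `functional_after`,
#'   `essential_recovered`, `missed_essential`, `recovery_fraction`,
#'   `category`.
#' @export
run_degradation_benchmark <- function(model,
                                      fractions = c(0.1, 0.2, 0.3, 0.4),
                                      rng_seeds = 1:3,
                                      biomass_zero_prob = 0.25,
                                      biomass_seed = rng_seeds[[1]],
                                      require_nonfunctional = TRUE,
                                      delta = 1, tol = 1e-6) {
  net <- model$network
  seeds <- model$seeds
  base_id <- model$biomass_id

  biomass <- random_biomass(net, base_id, biomass_zero_prob, biomass_seed)
  rxns <- net$reactions
  rxns[[base_id]] <- biomass
  ref <- met_network(unname(rxns), net$metabolites)

  ref_classes <- classify_reactions(build_flux_model(ref, seeds, base_id),
                                    delta, tol)
  targets <- names(biomass$reactants)

  rows <- list()
  for (fr in fractions) {
    for (sd in rng_seeds) {
      rec <- degrade(ref, fr, ref_classes, rng_seed = sd,
                     require_nonfunctional = require_nonfunctional,
                     biomass_id = base_id, seeds = seeds, tol = tol)
      # the biomass reaction is kept out of draft and database for the
      # topological step: its reactants are the targets
      draft_rxns <- rec$degraded$reactions[
        setdiff(reaction_ids(rec$degraded), base_id)]
      db_rxns <- ref$reactions[setdiff(reaction_ids(ref), base_id)]
      inst <- gap_fill_instance(met_network(unname(draft_rxns)),
                                met_network(unname(db_rxns)),
                                seeds = seeds, targets = targets)
      comp <- enumerate_minimal_completions(inst)
      fill_ids <- union(reaction_ids(rec$degraded), comp$union)
      filled <- met_network(unname(ref$reactions[
        intersect(reaction_ids(ref), union(fill_ids, base_id))]),
        ref$metabolites)
      ev <- evaluate_completion(rec, filled, base_id, seeds,
                                reference_classes = ref_classes,
                                delta = delta, tol = tol)
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = fr, rng_seed = sd,
        n_removed = length(rec$removed),
        removed_essential = rec$per_class_removed[["essential"]],
        removed_alternative = rec$per_class_removed[["alternative"]],
        removed_blocked = rec$per_class_removed[["blocked"]],
        optimum_size = comp$optimum_size,
        solution_size = ev$solution_size,
        functional_after = ev$functional_after,
        essential_recovered = ev$essential_recovered,
        missed_essential = ev$missed_essential,
        recovery_fraction = ev$recovery_fraction,
        category = ev$category,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
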