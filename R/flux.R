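# LP wrapper -----------------------------------------------------------------

# maximize c'v subject to S v = 0 rows (already built), lb <= v <= ub.
# Shifts to y = v - lb >= 0 and calls the compiled simplex.
lp_max <- function(cvec, Aeq, beq, lb, ub, max_iter = 50000L) {
  shift <- Aeq %*% lb
  res <- cpp_lp_max(cvec, Aeq, as.numeric(beq - shift),
                    as.numeric(ub - lb), max_iter = max_iter)
  if (res$status == 1L) return(list(feasible = FALSE, objective = NA_real_,
                                    v = NULL))
  if (res$status == 2L) stop("LP unbounded; check flux bounds", call. = FALSE)
  if (res$status == 3L) stop("LP iteration limit reached", call. = FALSE)
  v <- as.numeric(res$x) + lb
  list(feasible = TRUE, objective = sum(cvec * v), v = v)
}

# Flux model ------------------------------------------------------------------

#' Build a flux model from a network and seed nutrients
#'
#' Wraps a network into the data needed for linear-programming validation:
#' per-reaction flux bounds (reversible `[-bound, bound]`, irreversible
#' `[0, bound]`), a named objective reaction, and one import exchange
#' reaction per seed (bounds `[0, bound]`) so the growth medium can enter the
#' system. Boundary metabolites are excluded from the steady-state mass
#' balance. Construction is deterministic.
#'
#' @param net A `gs_network`.
#' @param seeds Character vector of seed metabolite ids.
#' @param objective_id Id of the objective (e.g. biomass) reaction; must
#'   exist in `net`.
#' @param bound Default flux bound magnitude (1000, the community
#'   convention).
#' @return An object of class `gs_flux_model` with `network`, `bounds`
#'   (matrix reactions x `lower`,`upper` including exchanges), `objective_id`
#'   and `exchange_ids`.
#' @export
build_flux_model <- function(net, seeds, objective_id, bound = 1000) {
  stopifnot(inherits(net, "gs_network"))
  if (!objective_id %in% reaction_ids(net)) {
    stop("objective reaction '", objective_id, "' not in network",
         call. = FALSE)
  }
  seeds <- unique(as.character(seeds))
  reactions <- net$reactions
  exchange_ids <- character()
  for (s in seeds) {
    ex_id <- paste0("EX_", s, "_import")
    while (ex_id %in% names(reactions)) ex_id <- paste0(ex_id, "_")
    reactions[[ex_id]] <- reaction(ex_id, products = stats::setNames(1, s))
    exchange_ids <- c(exchange_ids, ex_id)
  }
  mets <- net$metabolites
  extra <- setdiff(seeds, mets$id)
  if (length(extra)) {
    mets <- rbind(mets, data.frame(id = extra, name = NA_character_,
                                   boundary = FALSE, stringsAsFactors = FALSE))
  }
  full <- met_network(unname(reactions), mets)
  rids <- reaction_ids(full)
  bounds <- matrix(0, nrow = length(rids), ncol = 2,
                   dimnames = list(rids, c("lower", "upper")))
  for (r in full$reactions) {
    bounds[r$id, ] <- if (r$reversible) c(-bound, bound) else c(0, bound)
  }
  structure(list(network = full, bounds = bounds,
                 objective_id = objective_id, exchange_ids = exchange_ids),
            class = "gs_flux_model")
}

#' @export
print.gs_flux_model <- function(x, ...) {
  cat(sprintf("<flux model: %d reactions (%d exchanges), objective '%s'>\n",
              length(x$network$reactions), length(x$exchange_ids),
              x$objective_id))
  invisible(x)
}

# Stoichiometric matrix over non-boundary metabolites (rows) and all model
# reactions (columns).
flux_matrix <- function(model) {
  net <- model$network
  mets <- net$metabolites$id[!net$metabolites$boundary]
  rids <- reaction_ids(net)
  S <- matrix(0, nrow = length(mets), ncol = length(rids),
              dimnames = list(mets, rids))
  for (r in net$reactions) {
    re <- r$reactants[names(r$reactants) %in% mets]
    pr <- r$products[names(r$products) %in% mets]
    if (length(re)) S[names(re), r$id] <- S[names(re), r$id] - re
    if (length(pr)) S[names(pr), r$id] <- S[names(pr), r$id] + pr
  }
  S
}

#' Maximum objective flux (flux balance analysis)
#'
#' Maximizes the flux through the model's objective reaction subject to
#' steady-state mass balance on non-boundary metabolites and the flux
#' bounds. A network is called functional when the optimum exceeds the
#' tolerance. An infeasible program is reported as optimum 0 with
#' `infeasible = TRUE` rather than an error.
#'
#' @param model A `gs_flux_model`.
#' @return List with `objective` (numeric), `infeasible` (flag) and `fluxes`
#'   (named vector, `NULL` when infeasible).
#' @export
fba_max <- function(model) {
  stopifnot(inherits(model, "gs_flux_model"))
  S <- flux_matrix(model)
  rids <- colnames(S)
  cvec <- as.numeric(rids == model$objective_id)
  sol <- lp_max(cvec, S, rep(0, nrow(S)),
                model$bounds[rids, "lower"], model$bounds[rids, "upper"])
  if (!sol$feasible) {
    return(list(objective = 0, infeasible = TRUE, fluxes = NULL))
  }
  list(objective = sol$objective, infeasible = FALSE,
       fluxes = stats::setNames(sol$v, rids))
}

#' Classify reactions as essential, alternative or blocked
#'
#' Flux variability analysis over the feasible region `{steady state, bounds,
#' v_objective >= delta}`: for each network reaction the flux interval
#' `[lo, hi]` is computed; the reaction is `blocked` when `lo = hi = 0`,
#' `essential` when the interval excludes 0 (flux is always nonzero whenever
#' the objective is produced), and `alternative` otherwise. Classification is
#' relative to the model's objective (biomass) reaction and requires a
#' functional model. Exchange reactions created for seeds are not classified.
#'
#' @param model A `gs_flux_model`.
#' @param delta Minimum objective (biomass) flux defining the feasible
#'   region; default 1 flux unit.
#' @param tol LP tolerance below which a flux is treated as zero (1e-6).
#' @return Named character vector over network reaction ids with values
#'   `"essential"`, `"alternative"` or `"blocked"`.
#' @export
classify_reactions <- function(model, delta = 1, tol = 1e-6) {
  stopifnot(inherits(model, "gs_flux_model"))
  S <- flux_matrix(model)
  rids <- colnames(S)
  lb <- model$bounds[rids, "lower"]
  ub <- model$bounds[rids, "upper"]
  nb <- nrow(S)
  obj_idx <- match(model$objective_id, rids)

  # objective floor as an extra row with a surplus variable:
  # v_obj - s = delta, s in [0, ub_obj - delta]
  Aeq <- rbind(S, as.numeric(seq_along(rids) == obj_idx))
  Aeq <- cbind(Aeq, c(rep(0, nb), -1))
  beq <- c(rep(0, nb), delta)
  lb2 <- c(lb, 0)
  ub2 <- c(ub, max(ub[obj_idx] - delta, 0))

  base <- lp_max(rep(0, length(lb2)), Aeq, beq, lb2, ub2)
  if (!base$feasible) {
    stop("model cannot reach the required objective flux; ",
         "run fba_max() first", call. = FALSE)
  }

  classify_ids <- setdiff(rids, model$exchange_ids)
  # flux signs observed in any feasible solution let later reactions skip LPs
  seen_pos <- base$v[seq_along(rids)] > tol
  seen_neg <- base$v[seq_along(rids)] < -tol

  dir_opt <- function(j, maximize) {
    cvec <- rep(0, length(lb2))
    cvec[j] <- if (maximize) 1 else -1
    sol <- lp_max(cvec, Aeq, beq, lb2, ub2)
    # region already known feasible
    v <- sol$v
    seen_pos <<- seen_pos | v[seq_along(rids)] > tol
    seen_neg <<- seen_neg | v[seq_along(rids)] < -tol
    v[j]
  }

  labels <- stats::setNames(character(length(classify_ids)), classify_ids)
  for (rid in classify_ids) {
    j <- match(rid, rids)
    hi_pos <- seen_pos[j]
    lo_neg <- seen_neg[j]
    if (hi_pos && lo_neg) { labels[rid] <- "alternative"; next }
    hi <- if (hi_pos) tol * 2 else dir_opt(j, TRUE)
    lo <- if (seen_neg[j]) -tol * 2 else dir_opt(j, FALSE)
    labels[rid] <- if (abs(hi) <= tol && abs(lo) <= tol) "blocked"
      else if (lo > tol || hi < -tol) "essential"
      else "alternative"
  }
  labels
}
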