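#' Forward scope of a seed set
#'
#' Computes the least fixed point of topological producibility: a directed
#' reaction fires once all of its reactants are producible, and a metabolite
#' is producible if it is a seed or the product of a fired reaction. A
#' reaction with no reactants fires unconditionally. Stoichiometric
#' coefficients and boundary flags play no role; this is the purely
#' topological semantics, computed in time linear in the total reactant
#' degree by a counting queue.
#'
#' @param reactions A `gs_directed` set from [directed_view()] (a plain list
#'   with the same element structure is accepted).
#' @param seeds Character vector of seed metabolite ids (may be empty).
#' @return An object of class `gs_scope`: `producible` (metabolite ids, seeds
#'   included), `fired` (data frame `origin_id`, `direction` of reachable
#'   directed reactions) and `iterations` (number of breadth-first sweeps to
#'   the fixed point).
#' @examples
#' net <- met_network(list(reaction("R1", c(S = 1), c(T = 1))))
#' compute_scope(directed_view(net), "S")$producible
#' @export
compute_scope <- function(reactions, seeds) {
  seeds <- unique(as.character(seeds))
  env <- scope_index(reactions)
  res <- scope_run(env, seq_along(env$reac), seeds)
  fired_idx <- which(res$fired)
  structure(list(
    producible = res$producible,
    fired = data.frame(
      origin_id = env$origin[fired_idx],
      direction = env$direction[fired_idx],
      stringsAsFactors = FALSE),
    iterations = res$iterations), class = "gs_scope")
}

#' @export
print.gs_scope <- function(x, ...) {
  cat(sprintf("<scope: %d producible metabolites, %d fired reactions, %d sweeps>\n",
              length(x$producible), nrow(x$fired), x$iterations))
  invisible(x)
}

# Precomputed integer-indexed view of a directed reaction set, reused across
# the many scope calls the completion solver makes.
scope_index <- function(reactions) {
  stopifnot(is.list(reactions))
  mets <- unique(unlist(lapply(reactions, function(d) {
    c(d$reactants, d$products)
  }), use.names = FALSE))
  if (is.null(mets)) mets <- character()
  midx <- seq_along(mets)
  names(midx) <- mets
  reac <- lapply(reactions, function(d) unname(midx[d$reactants]))
  prod <- lapply(reactions, function(d) unname(midx[d$products]))
  feeds <- vector("list", length(mets))  # metabolite -> reactions it feeds
  for (i in seq_along(reac)) {
    for (m in reac[[i]]) feeds[[m]] <- c(feeds[[m]], i)
  }
  list(mets = mets, midx = midx,
       origin = vapply(reactions, function(d) d$origin_id, character(1)),
       direction = vapply(reactions, function(d) d$direction, character(1)),
       reac = reac, prod = prod, feeds = feeds,
       need0 = lengths(reac))
}

# Core fixed-point engine over an index. `active` selects the directed
# reactions allowed to fire. Seeds outside the indexed metabolite universe
# are producible but cannot enable anything, so they are re-appended at the
# end. Returns producible ids, fired flags (over all indexed reactions) and
# the sweep count.
scope_run <- function(env, active, seeds) {
  n_m <- length(env$mets)
  n_r <- length(env$reac)
  producible <- logical(n_m)
  fired <- logical(n_r)
  is_active <- logical(n_r)
  is_active[active] <- TRUE
  need <- env$need0

  seed_in <- seeds[seeds %in% env$mets]
  frontier <- unname(env$midx[seed_in])
  producible[frontier] <- TRUE
  # source reactions (no reactants) fire immediately
  ready <- which(is_active & need == 0L)
  iterations <- 0L

  repeat {
    new_mets <- integer()
    if (length(ready)) {
      fired[ready] <- TRUE
      for (i in ready) {
        for (m in env$prod[[i]]) {
          if (!producible[m]) {
            producible[m] <- TRUE
            new_mets <- c(new_mets, m)
          }
        }
      }
    }
    wave <- c(frontier, new_mets)
    frontier <- integer()
    if (!length(wave) && !length(ready)) break
    iterations <- iterations + 1L
    ready <- integer()
    for (m in wave) {
      for (i in env$feeds[[m]]) {
        need[i] <- need[i] - 1L
        if (is_active[i] && !fired[i] && need[i] == 0L) {
          ready <- c(ready, i)
        }
      }
    }
    if (!length(ready)) break
  }
  list(producible = c(env$mets[producible], setdiff(seeds, env$mets)),
       fired = fired, iterations = iterations)
}

#' Targets not producible from the seeds
#'
#' Detects gaps: the subset of targets outside the forward scope of the seeds
#' in the given network. An empty result means no gap-filling is needed.
#'
#' @param net A `gs_network`.
#' @param seeds,targets Character vectors of metabolite ids.
#' @return Character vector of unproducible target ids.
#' @export
unproducible_targets <- function(net, seeds, targets) {
  stopifnot(inherits(net, "gs_network"))
  sc <- compute_scope(directed_view(net), seeds)
  setdiff(unique(as.character(targets)), sc$producible)
}
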