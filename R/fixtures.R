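# Programmatic fixture generators: the two toy networks used throughout the
# documentation and tests, random planted gap-filling instances with known
# ground truth, and a mid-sized benchmark model for the degradation harness.

#' Toy gap-filling instance with five minimal completions
#'
#' A draft network producing nothing useful on its own, three targets
#' (`T1`, `T2`, `T3`), one seed (`S`) and a nine-reaction reference database
#' (`R1`..`R9`). The draft contains a two-metabolite cycle that must be fed
#' from outside (`R4` or `R6`) and closed by `R7` to produce `T1`; `T2` has
#' a short route (`R3`), a long route (`R1`+`R2`), and two parasitic routes
#' off the `T1` machinery (`R5`, `R8`); `T3` hangs off the cycle in the
#' draft. The minimum completion size is 3, with exactly five minimal
#' completions whose union has six reactions and whose intersection is
#' `{R7}`; `R9` (internal to the cycle) and the long route `R1`/`R2` never
#' appear in a minimal completion.
#'
#' @return A `gs_instance`.
#' @examples
#' res <- enumerate_minimal_completions(toy_instance())
#' res$optimum_size  # 3
#' @export
toy_instance <- function() {
  draft <- met_network(list(
    reaction("D1", c(m1 = 1), c(m2 = 1)),   # cycle edge m1 -> m2
    reaction("D2", c(m1 = 1), c(p = 1)),    # precursor of T3
    reaction("D3", c(p = 1), c(T3 = 1))
  ))
  database <- met_network(list(
    reaction("R1", c(S = 1), c(u = 1)),          # long route to T2 ...
    reaction("R2", c(u = 1), c(T2 = 1)),         # ... never parsimonious
    reaction("R3", c(S = 1), c(T2 = 1)),         # short route to T2
    reaction("R4", c(S = 1), c(m1 = 1, x4 = 1)), # feeds the cycle at m1
    reaction("R5", c(x4 = 1), c(T2 = 1)),        # rides on R4's byproduct
    reaction("R6", c(S = 1), c(m2 = 1)),         # feeds the cycle at m2
    reaction("R7", c(m2 = 1), c(m1 = 1, T1 = 1)),# closes the cycle, makes T1
    reaction("R8", c(T1 = 1), c(T2 = 1)),        # rides on T1
    reaction("R9", c(m2 = 1), c(m1 = 1))         # cycle-internal, never helps
  ))
  gap_fill_instance(draft, database, seeds = "S",
                    targets = c("T1", "T2", "T3"))
}

#' Producibility-semantics network contrasting scope and FBA
#'
#' A single-seed network on which the topological and the stoichiometric
#' producibility criteria disagree in both directions. The branch
#' `S -> n a + b`, `a + b -> d`, `a -> c`, `c + d -> T1` makes `T1`
#' scope-producible for any `n` but FBA-producible only at `n = 2` (and `d`
#' alone only at `n = 1`). The branch `S -> e`, `e -> T2 + f` leaves the
#' byproduct `f` without a consumer, so `T2` is scope-producible but
#' FBA-blocked. The cycle `j -> 2 k`, `k -> l`, `l -> j` amplifies itself
#' under flux balance, so `k` is FBA-producible but not scope-producible.
#' `T3` and `T4` (via `g`) are producible under both criteria. Objective
#' reactions `consume_T1`, `consume_T2`, `consume_T3T4` and `consume_k` are
#' included for flux tests.
#'
#' @param n Stoichiometric coefficient of `a` in the seed-consuming reaction.
#' @return List with `network` (a `gs_network`) and `seeds` (`"S"`).
#' @export
semantics_network <- function(n = 2) {
  stopifnot(n > 0)
  net <- met_network(list(
    reaction("v1", c(S = 1), c(a = n, b = 1)),
    reaction("v2", c(a = 1, b = 1), c(d = 1)),
    reaction("v3", c(a = 1), c(c = 1)),
    reaction("v4", c(c = 1, d = 1), c(T1 = 1)),
    reaction("v5", c(S = 1), c(e = 1)),
    reaction("v6", c(e = 1), c(T2 = 1, f = 1)),
    reaction("v7", c(j = 1), c(k = 2)),
    reaction("v8", c(k = 1), c(l = 1)),
    reaction("v9", c(l = 1), c(j = 1)),
    reaction("v10", c(S = 1), c(g = 1)),
    reaction("v11", c(g = 1), c(T3 = 1)),
    reaction("v12", c(g = 1), c(T4 = 1)),
    reaction("consume_T1", c(T1 = 1), numeric()),
    reaction("consume_T2", c(T2 = 1), numeric()),
    reaction("consume_T3T4", c(T3 = 1, T4 = 1), numeric()),
    reaction("consume_k", c(k = 1), numeric())
  ))
  list(network = net, seeds = "S")
}

#' Random planted gap-filling instance with known ground truth
#'
#' Builds a layered seed-to-target chain alternating single "bottleneck"
#' reactions and bundles of `width` parallel reactions. One bottleneck and
#' one full bundle are removed into the database, so every completion must
#' contain the bottleneck (`forced_reactions`) plus any one bundle member:
#' `planted_optimum = 2` and `planted_solutions` has `width` elements (with
#' no bundles, `n_layers < 2` degenerates to a single forced solution).
#' Distractor database reactions are added in equal proportion as
#' never-firable (consuming a fresh unproducible metabolite) and redundant
#' (duplicating a surviving draft conversion under a new id); neither kind
#' can enter a minimal completion.
#'
#' @param n_layers Number of bottleneck+bundle stages (>= 1).
#' @param width Number of parallel reactions per bundle (>= 1).
#' @param n_distractors Number of distractor database reactions.
#' @param rng_seed Integer seed; the construction is deterministic given it.
#' @return List of class `gs_planted`: `instance`, `planted_optimum`,
#'   `planted_solutions`, `forced_reactions`.
#' @export
planted_instance <- function(n_layers = 3, width = 2, n_distractors = 4,
                             rng_seed = 1) {
  stopifnot(n_layers >= 1, width >= 1, n_distractors >= 0)
  with_local_seed(rng_seed, {
    rxns <- list()
    prev <- "seed"
    for (i in seq_len(n_layers)) {
      bid <- sprintf("B%d", i)
      mid <- sprintf("b%d", i)
      rxns[[bid]] <- reaction(bid, stats::setNames(1, prev),
                              stats::setNames(1, mid))
      out <- sprintf("m%d", i)
      for (j in seq_len(width)) {
        pid <- sprintf("P%d_%d", i, j)
        rxns[[pid]] <- reaction(pid, stats::setNames(1, mid),
                                stats::setNames(1, out))
      }
      prev <- out
    }
    target <- prev

    cut_bottleneck <- sprintf("B%d", sample.int(n_layers, 1))
    cut_bundle <- if (n_layers >= 2) {
      layers <- setdiff(seq_len(n_layers),
                        as.integer(sub("B", "", cut_bottleneck)))
      sprintf("P%d_%d", sample(layers, 1), seq_len(width))
    } else character()
    removed <- c(cut_bottleneck, cut_bundle)

    db_rxns <- rxns[removed]
    draft_rxns <- rxns[setdiff(names(rxns), removed)]

    if (n_distractors > 0) {
      n_dead <- ceiling(n_distractors / 2)
      for (d in seq_len(n_distractors)) {
        did <- sprintf("X%d", d)
        if (d <= n_dead) {  # never firable: fresh unproducible reactant
          db_rxns[[did]] <- reaction(
            did, stats::setNames(1, sprintf("orphan%d", d)),
            stats::setNames(1, sprintf("orphan_out%d", d)))
        } else {            # redundant: duplicate of a surviving draft reaction
          src <- draft_rxns[[sample.int(length(draft_rxns), 1)]]
          db_rxns[[did]] <- reaction(did, src$reactants, src$products,
                                     reversible = src$reversible)
        }
      }
    }

    inst <- gap_fill_instance(met_network(unname(draft_rxns)),
                              met_network(unname(db_rxns)),
                              seeds = "seed", targets = target)
    sols <- if (length(cut_bundle)) {
      lapply(cut_bundle, function(p) sort(c(cut_bottleneck, p)))
    } else list(cut_bottleneck)
    key <- vapply(sols, paste, character(1), collapse = "\r")
    structure(list(instance = inst,
                   planted_optimum = length(sols[[1]]),
                   planted_solutions = sols[order(key, method = "radix")],
                   forced_reactions = cut_bottleneck),
              class = "gs_planted")
  })
}

#' Mid-sized benchmark model with known reaction classes
#'
#' A deterministic ~100-reaction model for the degradation benchmark: an
#' essential linear backbone from the seed to six biomass precursors, a set
#' of two-route (alternative) branches, and a blocked compartment of
#' reactions that can never carry steady-state flux (orphan reactants or
#' dead-end products). The biomass reaction `BIOMASS` consumes the
#' precursors. With the full biomass as objective the FVA classes (always
#' computed, never assumed) come out as: the load-bearing backbone and
#' precursor-joining steps essential, branch routes alternative, the
#' orphan/dead-end compartment plus the terminal backbone stub blocked
#' (13/61/26 at the defaults).
#'
#' @param n_alt_pairs Number of two-route alternative branches (default 20).
#' @param n_blocked Number of blocked reactions (default 25).
#' @return List: `network` (`gs_network`), `seeds` (`"nutrient"`),
#'   `biomass_id` (`"BIOMASS"`). The defaults give 100 reactions.
#' @export
benchmark_model <- function(n_alt_pairs = 20, n_blocked = 25) {
  rxns <- list()
  add <- function(id, from, to) {
    rxns[[id]] <<- reaction(id, stats::setNames(rep(1, length(from)), from),
                            stats::setNames(rep(1, length(to)), to))
  }
  # essential backbone: nutrient -> c1 -> ... -> c8
  chain <- c("nutrient", sprintf("c%d", 1:8))
  for (i in seq_len(length(chain) - 1)) {
    add(sprintf("E%d", i), chain[i], chain[i + 1])
  }
  # six precursors drawn from backbone intermediates, one essential step each
  precursors <- sprintf("prec%d", 1:6)
  for (k in seq_along(precursors)) {
    add(sprintf("EP%d", k), chain[2 + (k - 1) %% 7], precursors[k])
  }
  # alternative branches: aux metabolite reachable by two disjoint routes,
  # feeding a seventh, optional biomass precursor through an essential joiner
  for (k in seq_len(n_alt_pairs)) {
    src <- chain[2 + (k - 1) %% 7]
    aux <- sprintf("aux%d", k)
    add(sprintf("A%da", k), src, aux)
    add(sprintf("A%db", k), src, aux)
    add(sprintf("AJ%d", k), aux, "prec7")
  }
  # blocked compartment: orphan reactant or dead-end product
  for (k in seq_len(n_blocked)) {
    if (k %% 2 == 0) add(sprintf("BL%d", k), sprintf("orphan%d", k),
                         sprintf("bl_out%d", k))
    else add(sprintf("BL%d", k), chain[3], sprintf("deadend%d", k))
  }
  # biomass consumes the six essential precursors and the alternative one
  biomass_in <- stats::setNames(rep(1, 7), c(precursors, "prec7"))
  rxns[["BIOMASS"]] <- reaction("BIOMASS", biomass_in, numeric())
  list(network = met_network(unname(rxns)), seeds = "nutrient",
       biomass_id = "BIOMASS")
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
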