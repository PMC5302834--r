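#' Solver options for gap-filling
#'
#' @param enumeration_limit Optional cap on the number of solutions returned
#'   by [enumerate_minimal_completions()]. The internal enumeration is always
#'   complete, so `union`/`intersection` stay exact; the cap only truncates
#'   the reported list (flagged by `enumeration_truncated`).
#' @param time_budget Optional wall-clock budget in seconds; exceeding it
#'   raises a timeout error carrying the best bound found so far.
#' @param deterministic_order When `TRUE` (default) solutions are sorted
#'   lexicographically by their sorted reaction ids, making output
#'   byte-stable.
#' @return A list of class `gs_solver_options`.
#' @export
solver_options <- function(enumeration_limit = NULL, time_budget = NULL,
                           deterministic_order = TRUE) {
  if (!is.null(enumeration_limit)) {
    enumeration_limit <- as.integer(enumeration_limit)
    stopifnot(length(enumeration_limit) == 1L, enumeration_limit >= 1L)
  }
  structure(list(enumeration_limit = enumeration_limit,
                 time_budget = time_budget,
                 deterministic_order = isTRUE(deterministic_order)),
            class = "gs_solver_options")
}

timeout_error <- function(best_bound) {
  structure(class = c("gs_timeout", "error", "condition"),
            list(message = sprintf(
              "gap-filling time budget exceeded (best bound: %d)", best_bound),
              call = NULL, best_bound = best_bound))
}

deadline_check <- function(deadline, best_bound) {
  if (!is.null(deadline) && Sys.time() > deadline) stop(timeout_error(best_bound))
}

#' Split targets into reconstructable and unreconstructable
#'
#' A target is reconstructable when it lies in the scope of the seeds over
#' draft plus the full database; by monotonicity of the scope in the reaction
#' set, no subset of database reactions can produce anything more, so this is
#' the unique maximal producible target set. Unreconstructable targets are
#' excluded before minimization.
#'
#' @param inst A `gs_instance`.
#' @return List with character vectors `reconstructable` and
#'   `unreconstructable`.
#' @export
reconstructable_split <- function(inst) {
  stopifnot(inherits(inst, "gs_instance"))
  full <- merge_networks(inst$draft, inst$database)
  sc <- compute_scope(directed_view(full), inst$seeds)
  list(reconstructable = intersect(inst$targets, sc$producible),
       unreconstructable = setdiff(inst$targets, sc$producible))
}

# ---------------------------------------------------------------------------
# Internal exact solver.
#
# Strategy: (1) restrict candidates to database reactions that can ever fire
# (with everything added) and that are backward-relevant to the targets;
# (2) peel off "forced" reactions -- r is in every completion iff dropping r
# from the candidate pool loses a reconstructable target (scope monotonicity
# makes the full pool the most permissive context); (3) iterative-deepening
# exhaustive search over the small residual pool. Exactness is checked
# against a brute-force oracle in the test suite.
# ---------------------------------------------------------------------------

solver_state <- function(inst) {
  full <- merge_networks(inst$draft, inst$database)
  dirs <- directed_view(full)
  env <- scope_index(dirs)
  origin <- env$origin
  draft_ids <- reaction_ids(inst$draft)
  db_ids <- reaction_ids(inst$database)
  draft_dirs <- which(origin %in% draft_ids)
  dirs_of <- split(seq_along(origin), origin)
  list(env = env, draft_dirs = draft_dirs, dirs_of = dirs_of,
       db_ids = db_ids, seeds = inst$seeds)
}

state_scope <- function(st, add_ids) {
  active <- c(st$draft_dirs,
              unlist(st$dirs_of[add_ids], use.names = FALSE))
  scope_run(st$env, active, st$seeds)$producible
}

covers <- function(st, add_ids, targets) {
  all(targets %in% state_scope(st, add_ids))
}

# Candidates that can ever fire (with the already-forced reactions granted)
# and whose products can feed the targets.
prune_candidates <- function(st, pool, targets, base = character()) {
  if (!length(pool)) return(pool)
  # forward: directed reactions fired with the whole pool active
  active <- c(st$draft_dirs,
              unlist(st$dirs_of[c(base, pool)], use.names = FALSE))
  res <- scope_run(st$env, active, st$seeds)
  fired_origin <- unique(st$env$origin[res$fired])
  pool <- pool[pool %in% fired_origin]
  # backward: needed metabolites, walking producer reactions from the targets
  env <- st$env
  needed <- logical(length(env$mets))
  queue <- unname(env$midx[targets[targets %in% env$mets]])
  needed[queue] <- TRUE
  producers <- vector("list", length(env$mets))
  for (i in seq_along(env$prod)) {
    for (m in env$prod[[i]]) producers[[m]] <- c(producers[[m]], i)
  }
  relevant_dir <- logical(length(env$reac))
  while (length(queue)) {
    m <- queue[[1]]; queue <- queue[-1]
    for (i in producers[[m]]) {
      if (!relevant_dir[i]) {
        relevant_dir[i] <- TRUE
        for (mm in env$reac[[i]]) {
          if (!needed[mm]) { needed[mm] <- TRUE; queue <- c(queue, mm) }
        }
      }
    }
  }
  relevant_origin <- unique(env$origin[relevant_dir])
  pool[pool %in% relevant_origin]
}

# Reactions contained in every completion drawn from `pool`.
forced_in_pool <- function(st, base, pool, targets, deadline, best_bound) {
  forced <- character()
  for (r in pool) {
    deadline_check(deadline, best_bound)
    if (!covers(st, c(base, setdiff(pool, r)), targets)) forced <- c(forced, r)
  }
  forced
}

solve_completion <- function(inst, opts = solver_options()) {
  stopifnot(inherits(inst, "gs_instance"))
  if (!inherits(opts, "gs_solver_options")) opts <- do.call(solver_options, opts)
  deadline <- if (is.null(opts$time_budget)) NULL else
    Sys.time() + opts$time_budget

  split <- reconstructable_split(inst)
  targets <- split$reconstructable
  st <- solver_state(inst)

  if (!length(targets) || covers(st, character(), targets)) {
    return(finish_result(split, 0L, list(character()), opts))
  }

  pool <- sort(st$db_ids)
  forced <- character()
  repeat {
    pool <- prune_candidates(st, setdiff(pool, forced), targets, base = forced)
    f <- forced_in_pool(st, forced, pool, targets, deadline, length(forced))
    if (!length(f)) break
    forced <- c(forced, f)
    pool <- setdiff(pool, f)
    if (covers(st, forced, targets)) {
      return(finish_result(split, length(forced), list(sort(forced)), opts))
    }
  }

  # residual exhaustive search, iterative deepening on the completion size
  n <- length(pool)
  for (k in seq_len(n)) {
    deadline_check(deadline, length(forced))
    sols <- enumerate_k(st, forced, pool, targets, k, deadline)
    if (length(sols)) {
      sols <- lapply(sols, function(s) sort(c(forced, s)))
      return(finish_result(split, length(forced) + k, sols, opts))
    }
  }
  stop("no completion found for reconstructable targets; ",
       "this contradicts reconstructable_split", call. = FALSE)
}

# All k-subsets of pool (with forced already granted) covering the targets.
enumerate_k <- function(st, forced, pool, targets, k, deadline) {
  sols <- list()
  n <- length(pool)
  idx <- seq_len(k)
  repeat {
    deadline_check(deadline, length(forced))
    subset <- pool[idx]
    if (covers(st, c(forced, subset), targets)) {
      sols[[length(sols) + 1L]] <- subset
    }
    # next combination in lexicographic order
    p <- k
    while (p >= 1L && idx[p] == n - k + p) p <- p - 1L
    if (p < 1L) break
    idx[p] <- idx[p] + 1L
    if (p < k) idx[(p + 1L):k] <- idx[p] + seq_len(k - p)
  }
  sols
}

finish_result <- function(split, optimum, sols, opts) {
  if (opts$deterministic_order) {
    key <- vapply(sols, function(s) paste(s, collapse = "\r"), character(1))
    sols <- sols[order(key, method = "radix")]
  }
  union <- sort(unique(unlist(sols, use.names = FALSE)))
  if (is.null(union)) union <- character()
  inter <- if (length(sols)) sort(Reduce(intersect, sols)) else character()
  truncated <- FALSE
  if (!is.null(opts$enumeration_limit) && length(sols) > opts$enumeration_limit) {
    sols <- sols[seq_len(opts$enumeration_limit)]
    truncated <- TRUE
  }
  structure(list(
    reconstructable = split$reconstructable,
    unreconstructable = split$unreconstructable,
    optimum_size = as.integer(optimum),
    solutions = sols,
    union = union,
    intersection = inter,
    enumeration_truncated = truncated), class = "gs_completion")
}

#' @export
print.gs_completion <- function(x, ...) {
  cat(sprintf(paste0("<completion: optimum size %d, %d minimal set(s)%s, ",
                     "union %d, intersection %d, %d/%d targets reconstructable>\n"),
              x$optimum_size, length(x$solutions),
              if (x$enumeration_truncated) " (truncated)" else "",
              length(x$union), length(x$intersection),
              length(x$reconstructable),
              length(x$reconstructable) + length(x$unreconstructable)))
  invisible(x)
}

#' Minimum completion size
#'
#' The least number of database reactions whose addition to the draft makes
#' every reconstructable target producible from the seeds. Returns 0 when the
#' reconstructable targets are already in the draft scope. A reversible
#' database reaction counts once and grants both directions.
#'
#' @param inst A `gs_instance`.
#' @param opts A [solver_options()] list.
#' @return Non-negative integer.
#' @export
min_completion_size <- function(inst, opts = solver_options()) {
  solve_completion(inst, opts)$optimum_size
}

#' Enumerate all cardinality-minimal completions
#'
#' Exhaustively enumerates every distinct set of database reactions of
#' minimum cardinality that restores topological producibility of all
#' reconstructable targets, together with the union and intersection of the
#' solutions (brave and cautious consequences). Suboptimal (larger) sets are
#' never returned.
#'
#' @inheritParams min_completion_size
#' @return A `gs_completion` with fields `reconstructable`,
#'   `unreconstructable`, `optimum_size`, `solutions` (list of sorted
#'   reaction-id vectors), `union`, `intersection`,
#'   `enumeration_truncated`.
#' @export
enumerate_minimal_completions <- function(inst, opts = solver_options()) {
  solve_completion(inst, opts)
}

#' Union of all minimal completions
#'
#' Reactions appearing in at least one cardinality-minimal completion. This
#' set of candidate repair reactions is the tool's headline output for manual
#' curation.
#'
#' @inheritParams min_completion_size
#' @return Sorted character vector of reaction ids.
#' @export
union_of_minimal <- function(inst, opts = solver_options()) {
  solve_completion(inst, opts)$union
}

#' Intersection of all minimal completions
#'
#' Reactions appearing in every cardinality-minimal completion: those
#' indispensable to any parsimonious repair.
#'
#' @inheritParams min_completion_size
#' @return Sorted character vector of reaction ids.
#' @export
intersection_of_minimal <- function(inst, opts = solver_options()) {
  solve_completion(inst, opts)$intersection
}
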