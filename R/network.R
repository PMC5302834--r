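#' Create a metabolic reaction
#'
#' A reaction converts a multiset of reactant metabolites into a multiset of
#' product metabolites with positive stoichiometric coefficients. A metabolite
#' may appear on both sides (e.g. a catalytic carrier); the two entries are
#' kept distinct. Reversibility is a per-reaction flag: topological
#' computations expand a reversible reaction into two directed reactions, and
#' flux computations give it a negative lower bound.
#'
#' @param id Unique, non-empty reaction identifier.
#' @param reactants Named numeric vector: metabolite id -> coefficient (> 0).
#'   May be empty (a pure source reaction).
#' @param products Named numeric vector: metabolite id -> coefficient (> 0).
#'   May be empty (a pure sink reaction).
#' @param reversible Logical flag.
#' @param name Optional display name.
#' @return An object of class `gs_reaction`.
#' @examples
#' reaction("R1", c(A = 1), c(B = 2))
#' @export
reaction <- function(id, reactants = numeric(), products = numeric(),
                     reversible = FALSE, name = NULL) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id)) {
    stop("reaction id must be a single non-empty string", call. = FALSE)
  }
  reactants <- as_coef_vec(reactants, id, "reactants")
  products <- as_coef_vec(products, id, "products")
  if (length(reactants) == 0L && length(products) == 0L) {
    stop("reaction '", id, "': reactants and products cannot both be empty",
         call. = FALSE)
  }
  structure(
    list(id = id, reactants = reactants, products = products,
         reversible = isTRUE(reversible), name = name),
    class = "gs_reaction"
  )
}

as_coef_vec <- function(x, rid, side) {
  if (length(x) == 0L) return(stats::setNames(numeric(), character()))
  x <- unlist(x)
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("reaction '", rid, "': ", side, " must be a named vector", call. = FALSE)
  }
  storage.mode(x) <- "double"
  if (any(is.na(x)) || any(x <= 0)) {
    stop("reaction '", rid, "': ", side,
         " coefficients must be strictly positive", call. = FALSE)
  }
  if (anyDuplicated(names(x))) {
    x <- tapply(x, names(x), sum)  # collapse duplicate metabolite entries
    x <- stats::setNames(as.numeric(x), names(x))
  }
  x
}

#' Create a metabolic network
#'
#' A metabolic network is a bipartite directed graph between reactions and
#' metabolites. Every metabolite referenced by a reaction is registered;
#' additional isolated metabolites (e.g. from a seeds file) may be declared
#' explicitly.
#'
#' @param reactions List of [reaction()] objects.
#' @param metabolites Optional data frame with columns `id`, and optionally
#'   `name` and `boundary` (logical; boundary-condition species are excluded
#'   from steady-state balance in flux validation). Metabolites referenced by
#'   reactions are added automatically with `boundary = FALSE`.
#' @return An object of class `gs_network` with elements `reactions` (named
#'   list) and `metabolites` (data frame `id`, `name`, `boundary`).
#' @examples
#' net <- met_network(list(reaction("R1", c(A = 1), c(B = 1))))
#' @export
met_network <- function(reactions = list(), metabolites = NULL) {
  if (inherits(reactions, "gs_reaction")) reactions <- list(reactions)
  ids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate reaction ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(reactions) <- ids
  referenced <- unique(unlist(lapply(reactions, function(r) {
    c(names(r$reactants), names(r$products))
  }), use.names = FALSE))
  if (is.null(referenced)) referenced <- character()

  met <- normalize_met_table(metabolites)
  extra <- setdiff(referenced, met$id)
  if (length(extra)) {
    met <- rbind(met, data.frame(id = extra, name = NA_character_,
                                 boundary = FALSE, stringsAsFactors = FALSE))
  }
  rownames(met) <- NULL
  structure(list(metabolites = met, reactions = reactions),
            class = "gs_network")
}

normalize_met_table <- function(metabolites) {
  if (is.null(metabolites)) {
    return(data.frame(id = character(), name = character(),
                      boundary = logical(), stringsAsFactors = FALSE))
  }
  if (is.character(metabolites)) {
    metabolites <- data.frame(id = metabolites, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(metabolites), "id" %in% names(metabolites))
  if (any(!nzchar(metabolites$id)) || anyDuplicated(metabolites$id)) {
    stop("metabolite ids must be non-empty and unique", call. = FALSE)
  }
  if (is.null(metabolites$name)) metabolites$name <- NA_character_
  if (is.null(metabolites$boundary)) metabolites$boundary <- FALSE
  metabolites[, c("id", "name", "boundary")]
}

#' @export
print.gs_network <- function(x, ...) {
  nrev <- sum(vapply(x$reactions, function(r) r$reversible, logical(1)))
  cat(sprintf("<metabolic network: %d metabolites, %d reactions (%d reversible)>\n",
              nrow(x$metabolites), length(x$reactions), nrev))
  invisible(x)
}

#' @export
format.gs_reaction <- function(x, ...) {
  side <- function(v) {
    if (!length(v)) return("")
    paste(ifelse(v == 1, names(v), paste0(v, " ", names(v))), collapse = " + ")
  }
  arrow <- if (x$reversible) "<->" else "->"
  sprintf("%s: %s %s %s", x$id, side(x$reactants), arrow, side(x$products))
}

#' @export
print.gs_reaction <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

reaction_ids <- function(net) names(net$reactions)
metabolite_ids <- function(net) net$metabolites$id

same_reaction <- function(a, b) {
  eq_side <- function(x, y) {
    length(x) == length(y) && setequal(names(x), names(y)) &&
      isTRUE(all.equal(as.numeric(x[names(y)]), as.numeric(y), tolerance = 1e-9))
  }
  a$reversible == b$reversible &&
    eq_side(a$reactants, b$reactants) && eq_side(a$products, b$products)
}

#' Merge two metabolic networks
#'
#' The merged network has the union of metabolites and reactions. Reaction ids
#' shared by both networks must have identical definitions (same sides,
#' coefficients and reversibility); otherwise an error lists the offending
#' ids. A metabolite is a boundary species in the merge if it is flagged as
#' such in either input. Merging is idempotent and commutative up to ordering.
#'
#' @param a,b `gs_network` objects.
#' @return A `gs_network`.
#' @export
merge_networks <- function(a, b) {
  stopifnot(inherits(a, "gs_network"), inherits(b, "gs_network"))
  shared <- intersect(reaction_ids(a), reaction_ids(b))
  bad <- shared[!vapply(shared, function(id) {
    same_reaction(a$reactions[[id]], b$reactions[[id]])
  }, logical(1))]
  if (length(bad)) {
    stop("conflicting definitions for shared reaction ids: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  reactions <- c(a$reactions, b$reactions[setdiff(reaction_ids(b), shared)])
  met <- rbind(a$metabolites,
               b$metabolites[!(b$metabolites$id %in% a$metabolites$id), ])
  # boundary flag: TRUE wins across inputs
  bdry_b <- b$metabolites$boundary[match(met$id, b$metabolites$id)]
  met$boundary <- met$boundary | !is.na(bdry_b) & bdry_b
  met_network(unname(reactions), met)
}

#' Expand a network into directed reactions
#'
#' Each reaction contributes one forward directed reaction; each reversible
#' reaction additionally contributes a backward one with swapped sides.
#' Stoichiometric coefficients are dropped: directed reactions carry topology
#' only and are the input of [compute_scope()].
#'
#' @param net A `gs_network`.
#' @return A list of class `gs_directed`: each element has `origin_id`,
#'   `direction` (`"forward"` or `"backward"`), `reactants` and `products`
#'   (character vectors of metabolite ids).
#' @export
directed_view <- function(net) {
  stopifnot(inherits(net, "gs_network"))
  out <- vector("list", 0L)
  for (r in net$reactions) {
    out[[length(out) + 1L]] <- list(
      origin_id = r$id, direction = "forward",
      reactants = names(r$reactants), products = names(r$products))
    if (r$reversible) {
      out[[length(out) + 1L]] <- list(
        origin_id = r$id, direction = "backward",
        reactants = names(r$products), products = names(r$reactants))
    }
  }
  structure(out, class = "gs_directed")
}

#' Create a gap-filling problem instance
#'
#' Bundles the draft network, the reference reaction database, the seed
#' nutrients and the target metabolites. Seeds or targets absent from
#' draft and database are kept as isolated metabolites: a target no reaction
#' can produce is simply reported as unreconstructable. A reaction id present
#' in both draft and database must have the same definition; the database copy
#' is then dropped (the reference database typically embeds the model it
#' completes).
#'
#' @param draft,database `gs_network` objects.
#' @param seeds,targets Non-empty character vectors of metabolite ids.
#' @return An object of class `gs_instance`.
#' @export
gap_fill_instance <- function(draft, database, seeds, targets) {
  stopifnot(inherits(draft, "gs_network"), inherits(database, "gs_network"))
  seeds <- unique(as.character(seeds))
  targets <- unique(as.character(targets))
  if (!length(seeds) || !length(targets)) {
    stop("seeds and targets must be non-empty", call. = FALSE)
  }
  shared <- intersect(reaction_ids(draft), reaction_ids(database))
  bad <- shared[!vapply(shared, function(id) {
    same_reaction(draft$reactions[[id]], database$reactions[[id]])
  }, logical(1))]
  if (length(bad)) {
    stop("draft and database disagree on reaction ids: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(shared)) {
    keep <- setdiff(reaction_ids(database), shared)
    database <- met_network(unname(database$reactions[keep]),
                            database$metabolites)
  }
  structure(list(draft = draft, database = database,
                 seeds = seeds, targets = targets),
            class = "gs_instance")
}

#' @export
print.gs_instance <- function(x, ...) {
  cat(sprintf(paste0("<gap-filling instance: draft %d rxns, database %d rxns, ",
                     "%d seeds, %d targets>\n"),
              length(x$draft$reactions), length(x$database$reactions),
              length(x$seeds), length(x$targets)))
  invisible(x)
}
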