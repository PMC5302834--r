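# Independent oracles used across the suite. These deliberately avoid the
# package's engine internals: the scope oracle is a naive sweep-to-fixpoint
# over the reaction list, the completion oracle is exhaustive subset search,
# and the flux oracles re-solve the LPs with pracma::linprog (a different
# solver and formulation).

# naive scope: repeat full sweeps until nothing changes
oracle_scope <- function(net, seeds) {
  dirs <- list()
  for (r in net$reactions) {
    dirs[[length(dirs) + 1L]] <- list(re = names(r$reactants),
                                      pr = names(r$products))
    if (r$reversible) {
      dirs[[length(dirs) + 1L]] <- list(re = names(r$products),
                                        pr = names(r$reactants))
    }
  }
  producible <- unique(seeds)
  repeat {
    new <- producible
    for (d in dirs) {
      if (all(d$re %in% producible)) new <- union(new, d$pr)
    }
    if (length(new) == length(producible)) return(sort(producible))
    producible <- new
  }
}

# exhaustive minimal-completion search; mirrors the problem statement only
oracle_completions <- function(inst) {
  full <- merge_networks(inst$draft, inst$database)
  recon <- intersect(inst$targets, oracle_scope(full, inst$seeds))
  db <- sort(names(inst$database$reactions))
  covered <- function(ids) {
    net <- met_network(unname(c(inst$draft$reactions,
                                inst$database$reactions[ids])))
    all(recon %in% oracle_scope(net, inst$seeds))
  }
  if (!length(recon) || covered(character())) {
    return(list(reconstructable = recon, optimum = 0L,
                solutions = list(character())))
  }
  for (k in seq_along(db)) {
    sols <- list()
    cmb <- utils::combn(db, k, simplify = FALSE)
    for (s in cmb) if (covered(s)) sols[[length(sols) + 1L]] <- s
    if (length(sols)) {
      key <- vapply(sols, paste, character(1), collapse = "\r")
      return(list(reconstructable = recon, optimum = k,
                  solutions = sols[order(key, method = "radix")]))
    }
  }
  stop("oracle found no completion")
}

# random gap-filling instance small enough for the oracle
random_instance <- function(seed, n_mets = 8, n_draft = 4, n_db = 8) {
  set.seed(seed)
  mets <- sprintf("m%d", seq_len(n_mets))
  mk <- function(id) {
    re <- sample(mets, sample(1:2, 1))
    pr <- sample(setdiff(mets, re), sample(1:2, 1))
    reaction(id, stats::setNames(rep(1, length(re)), re),
             stats::setNames(rep(1, length(pr)), pr),
             reversible = stats::runif(1) < 0.2)
  }
  draft <- met_network(lapply(sprintf("d%d", seq_len(n_draft)), mk))
  db <- met_network(lapply(sprintf("r%d", seq_len(n_db)), mk))
  seeds <- sample(mets, 2)
  targets <- sample(setdiff(mets, seeds), 2)
  gap_fill_instance(draft, db, seeds, targets)
}

# LP oracle: maximize c'v s.t. S v = 0, lb <= v <= ub, optional objective
# floor, via pracma::linprog. pracma assumes x >= 0, so v is split into
# forward and backward non-negative parts with bounds written as rows.
oracle_lp_max <- function(cvec, S, lb, ub, floor_idx = NULL, delta = NULL) {
  n <- length(cvec)
  if (all(lb >= 0)) {  # no reversible flux: keep the natural x >= 0 form
    A <- diag(n)
    b <- ub
    if (!is.null(floor_idx)) {
      row <- rep(0, n)
      row[floor_idx] <- -1
      A <- rbind(A, row)
      b <- c(b, -delta)
    }
    r <- tryCatch(
      pracma::linprog(cvec, A = A, b = b, Aeq = S, beq = rep(0, nrow(S)),
                      maximize = TRUE, maxiter = 10000),
      error = function(e) NULL)
    if (is.null(r) || r$errno != 1) return(NULL)
    return(list(objective = sum(cvec * r$x), v = r$x))
  }
  cc <- c(cvec, -cvec)
  Ssplit <- cbind(S, -S)
  up <- pmax(ub, 0)
  dn <- pmax(-lb, 0)
  A <- rbind(cbind(diag(n), matrix(0, n, n)),
             cbind(matrix(0, n, n), diag(n)))
  b <- c(up, dn)
  if (!is.null(floor_idx)) {
    row <- rep(0, 2 * n)
    row[floor_idx] <- -1
    row[n + floor_idx] <- 1
    A <- rbind(A, row)
    b <- c(b, -delta)
  }
  r <- tryCatch(
    pracma::linprog(cc, A = A, b = b, Aeq = Ssplit, beq = rep(0, nrow(S)),
                    maximize = TRUE, maxiter = 10000),
    error = function(e) NULL)
  if (is.null(r) || r$errno != 1) return(NULL)
  v <- r$x[seq_len(n)] - r$x[n + seq_len(n)]
  list(objective = sum(cvec * v), v = v)
}

oracle_model_parts <- function(model) {
  S <- gapscope:::flux_matrix(model)
  rids <- colnames(S)
  list(S = S, rids = rids,
       lb = model$bounds[rids, "lower"], ub = model$bounds[rids, "upper"])
}

# FVA-by-pracma classification of the non-exchange reactions
oracle_classify <- function(model, delta = 1, tol = 1e-6) {
  p <- oracle_model_parts(model)
  obj_idx <- match(model$objective_id, p$rids)
  ids <- setdiff(p$rids, model$exchange_ids)
  out <- stats::setNames(character(length(ids)), ids)
  for (rid in ids) {
    j <- match(rid, p$rids)
    cv <- rep(0, length(p$rids))
    cv[j] <- 1
    hi <- oracle_lp_max(cv, p$S, p$lb, p$ub, obj_idx, delta)$objective
    lo <- -oracle_lp_max(-cv, p$S, p$lb, p$ub, obj_idx, delta)$objective
    out[rid] <- if (abs(hi) <= tol && abs(lo) <= tol) "blocked"
      else if (lo > tol || hi < -tol) "essential"
      else "alternative"
  }
  out
}

# knock-out essentiality: pin v_r to 0 and re-run FBA through the package
knockout_essential <- function(model, rid, delta = 1) {
  m <- model
  m$bounds[rid, ] <- c(0, 0)
  fba_max(m)$objective <= delta + 1e-9
}

# deterministic random flux model guaranteed functional for classification
random_flux_model <- function(seed, n_extra = 8, delta = 1) {
  set.seed(seed)
  mets <- sprintf("x%d", 1:6)
  rxns <- list(
    reaction("spine1", c(S = 1), c(x1 = 1)),
    reaction("spine2", c(x1 = 1), c(T = 1)),
    reaction("bio", c(T = 1), numeric()))
  for (i in seq_len(n_extra)) {
    re <- sample(c("S", mets), 1)
    pr <- sample(setdiff(c(mets, "T"), re), 1)
    rxns[[length(rxns) + 1L]] <- reaction(
      sprintf("e%d", i), stats::setNames(1, re), stats::setNames(1, pr),
      reversible = stats::runif(1) < 0.25)
  }
  net <- met_network(rxns)
  build_flux_model(net, "S", "bio")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_same_sets <- function(a, b) {
  norm <- function(x) {
    key <- vapply(x, function(s) paste(sort(s), collapse = "\r"), character(1))
    sort(key)
  }
  expect_identical(norm(a), norm(b))
}
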