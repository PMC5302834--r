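test_that("the toy instance is solved by exactly the five known minimal sets", {
  res <- enumerate_minimal_completions(toy_instance())
  expect_identical(res$optimum_size, 3L)
  expect_same_sets(res$solutions, list(
    c("R3", "R4", "R7"), c("R3", "R6", "R7"), c("R4", "R5", "R7"),
    c("R6", "R7", "R8"), c("R4", "R7", "R8")))
  expect_identical(res$union, c("R3", "R4", "R5", "R6", "R7", "R8"))
  expect_identical(res$intersection, "R7")
  expect_setequal(res$reconstructable, c("T1", "T2", "T3"))
  expect_length(res$unreconstructable, 0L)
  expect_false(res$enumeration_truncated)
})

test_that("already-producible targets need an empty completion", {
  draft <- met_network(list(reaction("R", c(S = 1), c(T = 1))))
  db <- met_network(list(reaction("X", c(S = 1), c(Y = 1))))
  inst <- gap_fill_instance(draft, db, "S", "T")
  res <- enumerate_minimal_completions(inst)
  expect_identical(res$optimum_size, 0L)
  expect_identical(res$solutions, list(character()))
  expect_identical(min_completion_size(inst), 0L)
})

test_that("targets no reaction can produce are split out as unreconstructable", {
  draft <- met_network(list(reaction("R", c(S = 1), c(A = 1))))
  db <- met_network(list(reaction("D", c(A = 1), c(T = 1))))
  inst <- gap_fill_instance(draft, db, "S", c("T", "GHOST"))
  sp <- reconstructable_split(inst)
  expect_identical(sp$reconstructable, "T")
  expect_identical(sp$unreconstructable, "GHOST")
  res <- enumerate_minimal_completions(inst)
  expect_identical(res$solutions, list("D"))
  expect_identical(res$unreconstructable, "GHOST")

  # empty database: reconstructable = already-in-draft-scope targets
  inst2 <- gap_fill_instance(draft, met_network(), "S", c("A", "T"))
  sp2 <- reconstructable_split(inst2)
  expect_identical(sp2$reconstructable, "A")
  expect_identical(sp2$unreconstructable, "T")
})

test_that("no database subset produces a target outside the reconstructable set", {
  for (seed in 1:10) {
    inst <- random_instance(seed)
    sp <- reconstructable_split(inst)
    db <- names(inst$database$reactions)
    set.seed(seed)
    for (i in 1:5) {
      sub <- sample(db, sample.int(length(db), 1))
      net <- met_network(unname(c(inst$draft$reactions,
                                  inst$database$reactions[sub])))
      sc <- compute_scope(directed_view(net), inst$seeds)
      expect_length(
        intersect(sp$unreconstructable, sc$producible), 0L)
    }
  }
})

test_that("enumeration agrees exactly with the brute-force oracle", {
  for (seed in 1:40) {
    inst <- random_instance(seed)
    expected <- oracle_completions(inst)
    got <- enumerate_minimal_completions(inst)
    expect_identical(got$optimum_size, as.integer(expected$optimum))
    expect_same_sets(got$solutions, expected$solutions)
    expect_identical(got$union,
                     sort(unique(unlist(expected$solutions))) %||% character())
    expect_identical(got$intersection,
                     sort(Reduce(intersect, expected$solutions)))
    expect_identical(union_of_minimal(inst), got$union)
    expect_identical(intersection_of_minimal(inst), got$intersection)
  }
})

test_that("returned solutions are sound and subset-minimal", {
  for (seed in c(2, 7, 13, 21)) {
    inst <- random_instance(seed)
    res <- enumerate_minimal_completions(inst)
    for (sol in res$solutions) {
      net <- met_network(unname(c(inst$draft$reactions,
                                  inst$database$reactions[sol])))
      sc <- compute_scope(directed_view(net), inst$seeds)$producible
      expect_true(all(res$reconstructable %in% sc))  # soundness
      for (r in sol) {                               # minimality
        net2 <- met_network(unname(c(inst$draft$reactions,
                                     inst$database$reactions[setdiff(sol, r)])))
        sc2 <- compute_scope(directed_view(net2), inst$seeds)$producible
        expect_false(all(res$reconstructable %in% sc2))
      }
    }
  }
})

test_that("solutions are consistent with union/intersection and byte-stable", {
  inst <- toy_instance()
  res <- enumerate_minimal_completions(inst)
  for (sol in res$solutions) {
    expect_true(all(res$intersection %in% sol))
    expect_true(all(sol %in% res$union))
  }
  res2 <- enumerate_minimal_completions(inst)
  expect_identical(res, res2)
})

test_that("a necessary reaction appears in every minimal completion", {
  # removing r from draft+database must place r in the intersection
  for (seed in c(1, 5, 9)) {
    pl <- planted_instance(n_layers = 3, width = 2, n_distractors = 4,
                           rng_seed = seed)
    inst <- pl$instance
    full <- merge_networks(inst$draft, inst$database)
    res <- enumerate_minimal_completions(inst)
    for (r in names(inst$database$reactions)) {
      without <- met_network(unname(full$reactions[
        setdiff(names(full$reactions), r)]), full$metabolites)
      broken <- unproducible_targets(without, inst$seeds, res$reconstructable)
      if (length(broken)) expect_true(r %in% res$intersection)
    }
  }
})

test_that("moving draft reactions into the database never shrinks the optimum", {
  for (seed in c(3, 11)) {
    inst <- random_instance(seed)
    base <- min_completion_size(inst)
    draft_ids <- names(inst$draft$reactions)
    set.seed(seed)
    drop <- sample(draft_ids, 2)
    smaller_draft <- met_network(unname(inst$draft$reactions[
      setdiff(draft_ids, drop)]))
    bigger_db <- merge_networks(inst$database,
                                met_network(unname(inst$draft$reactions[drop])))
    inst2 <- gap_fill_instance(smaller_draft, bigger_db,
                               inst$seeds, inst$targets)
    expect_gte(min_completion_size(inst2), base)
  }
})

test_that("a reversible database reaction costs one whichever direction is used", {
  db <- met_network(list(reaction("rev", c(A = 1), c(B = 1),
                                  reversible = TRUE)))
  # backward direction (B -> A) closes the gap
  back <- gap_fill_instance(
    met_network(list(reaction("mk", c(S = 1), c(B = 1)),
                     reaction("use", c(A = 1), c(T = 1)))),
    db, "S", "T")
  res_b <- enumerate_minimal_completions(back)
  expect_identical(res_b$optimum_size, 1L)
  expect_identical(res_b$solutions, list("rev"))
  # forward direction (A -> B) closes the mirrored gap at the same cost
  fwd <- gap_fill_instance(
    met_network(list(reaction("mk", c(S = 1), c(A = 1)),
                     reaction("use", c(B = 1), c(T = 1)))),
    db, "S", "T")
  res_f <- enumerate_minimal_completions(fwd)
  expect_identical(res_f$optimum_size, 1L)
  expect_identical(res_f$solutions, list("rev"))
})

test_that("the enumeration cap truncates the list but not union/intersection", {
  inst <- toy_instance()
  res <- enumerate_minimal_completions(inst,
                                       solver_options(enumeration_limit = 2))
  expect_length(res$solutions, 2L)
  expect_true(res$enumeration_truncated)
  expect_identical(res$union, c("R3", "R4", "R5", "R6", "R7", "R8"))
  expect_identical(res$intersection, "R7")
})

test_that("an exhausted time budget raises a typed timeout error", {
  inst <- toy_instance()
  expect_error(
    enumerate_minimal_completions(inst, solver_options(time_budget = -1)),
    class = "gs_timeout")
})
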