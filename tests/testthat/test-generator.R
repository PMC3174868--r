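test_that("methane is the unique CH4 constitution", {
  res <- enumerate_constitutions("CH4", atom_specs("C1", "C", 4L))
  expect_length(res$keys, 1L)
  expect_identical(res$keys[1], canonical_key(methane()))
  oracle <- brute_force_enumerate("CH4", atom_specs("C1", "C", 4L))
  expect_setequal(res$keys, oracle$keys)
})

test_that("the ethanol micro-problem has exactly one solution", {
  at <- atom_specs(c("C1", "C2"), "C", c(3L, 2L), "sp3")
  cns <- compile_constraints(
    correlation_set(cosy = list(c("C1", "C2")),
                    hmbc = list(c("C1", "C2"))), at
  )
  res <- enumerate_constitutions("C2H6O", at, cns)
  expect_length(res$keys, 1L)
  expect_identical(res$keys[1], canonical_key(ethanol()))
})

test_that("unconstrained C2H6O with fixed H counts gives the oracle-frozen set", {
  at <- atom_specs(c("C1", "C2"), "C", c(3L, 2L), "sp3")
  res <- enumerate_constitutions("C2H6O", at)
  oracle <- brute_force_enumerate("C2H6O", at)
  expect_setequal(res$keys, oracle$keys)
  # frozen regression value computed by the brute-force oracle: with n_h fixed
  # at (3, 2) and sp3 carbons, ethanol is the only connected valence-legal
  # arrangement of {C, C, O}
  expect_length(oracle$keys, 1L)
  expect_identical(oracle$keys[1], canonical_key(ethanol()))
})

test_that("propane is recovered from its own forward correlations", {
  prob <- toy_problem(propane())
  res <- enumerate_constitutions(prob$formula, prob$specs, prob$constraints)
  expect_true(canonical_key(propane()) %in% res$keys)
  oracle <- brute_force_enumerate(prob$formula, prob$specs, prob$constraints)
  expect_setequal(res$keys, oracle$keys)
})

test_that("generator and brute-force oracle agree on seeded toy inputs", {
  toys <- make_toy_structures(101, 8, c(2, 5))
  for (m in toys) {
    prob <- toy_problem(m)
    fast <- enumerate_constitutions(prob$formula, prob$specs,
                                    prob$constraints)
    slow <- brute_force_enumerate(prob$formula, prob$specs,
                                  prob$constraints)
    expect_setequal(fast$keys, slow$keys)
  }
})

test_that("every generated constitution is valid and mass-balanced", {
  for (m in make_toy_structures(55, 4, c(3, 5))) {
    prob <- toy_problem(m)
    res <- enumerate_constitutions(prob$formula, prob$specs,
                                   prob$constraints)
    for (cand in res$constitutions) {
      expect_silent(validate_constitution(cand))
      expect_identical(constitution_formula(cand), prob$formula)
      expect_identical(graph_dbe(cand), dbe(prob$formula))
    }
    expect_identical(length(res$keys), length(unique(res$keys)))
  }
})

test_that("adding a constraint never enlarges the candidate set", {
  set.seed(202)
  toys <- make_toy_structures(202, 5, c(3, 5))
  for (m in toys) {
    prob <- toy_problem(m)
    if (nrow(prob$constraints) < 2) next
    drop <- sample(nrow(prob$constraints), 1L)
    fewer <- prob$constraints[-drop, ]
    full_set <- enumerate_constitutions(prob$formula, prob$specs,
                                        prob$constraints)
    loose_set <- enumerate_constitutions(prob$formula, prob$specs, fewer)
    expect_true(all(full_set$keys %in% loose_set$keys))
  }
})

test_that("open atom types yield a superset of fixed atom types", {
  for (m in make_toy_structures(303, 5, c(3, 5))) {
    prob <- toy_problem(m)
    fixed <- enumerate_constitutions(prob$formula, prob$specs,
                                     prob$constraints)
    open <- enumerate_constitutions(prob$formula, prob$specs,
                                    prob$constraints,
                                    generation_config(open_types = TRUE))
    expect_true(all(fixed$keys %in% open$keys))
  }
})

test_that("the result set is independent of atom input order", {
  m <- make_toy_structures(77, 1, c(4, 5))[[1]]
  prob <- toy_problem(m)
  res1 <- enumerate_constitutions(prob$formula, prob$specs,
                                  prob$constraints)
  perm <- rev(seq_len(nrow(prob$specs)))
  res2 <- enumerate_constitutions(prob$formula, prob$specs[perm, ],
                                  prob$constraints)
  expect_setequal(res1$keys, res2$keys)
})

test_that("infeasible inputs fail before search", {
  # more fixed protons than the formula supplies
  expect_error(
    enumerate_constitutions("C2H4", atom_specs(c("C1", "C2"), "C",
                                               c(3L, 3L))),
    class = "nmrcase_infeasible_error"
  )
  # mandatory adjacency beyond an atom's free valence
  at <- atom_specs(c("C1", "C2", "C3", "C4", "C5"), "C",
                   c(1L, 3L, 3L, 3L, 3L), "sp3")
  cns <- compile_constraints(
    correlation_set(cosy = list(c("C1", "C2"), c("C1", "C3"),
                                c("C1", "C4"), c("C1", "C5"))), at
  )
  expect_error(
    enumerate_constitutions("C5H13N", at, cns),
    class = "nmrcase_infeasible_error"
  )
  # leftover hydrogens with nowhere to go
  expect_error(
    enumerate_constitutions("C2H6", atom_specs(c("C1", "C2"), "C",
                                               c(3L, 2L))),
    class = "nmrcase_infeasible_error"
  )
})

test_that("the oracle refuses inputs beyond its size limit", {
  at <- atom_specs(paste0("C", 1:8), "C", rep(2L, 8))
  expect_error(brute_force_enumerate("C8H18", at, limit = 7L),
               class = "nmrcase_oracle_limit_error")
})

test_that("max_results truncation is flagged, never silent", {
  at <- atom_specs(c("C1", "C2", "C3", "C4"), "C", NA_integer_)
  res <- enumerate_constitutions("C4H10O", at,
                                 config = generation_config(max_results = 2))
  expect_true(res$meta$truncated)
  expect_length(res$keys, 2L)
  full <- enumerate_constitutions("C4H10O", at)
  expect_false(full$meta$truncated)
  expect_gt(length(full$keys), 2L)
})

test_that("min_ring_size excludes small rings", {
  # cyclopropane vs propene from C3H6 with open types
  at <- atom_specs(paste0("C", 1:3), "C", NA_integer_)
  all_r <- enumerate_constitutions("C3H6", at)
  no3 <- enumerate_constitutions("C3H6", at,
                                 config = generation_config(min_ring_size = 4))
  expect_gt(length(all_r$keys), length(no3$keys))
  expect_true(all(vapply(no3$constitutions, function(m) {
    smallest_ring_size(m) >= 4
  }, logical(1))))
})

test_that("heteroatom-heteroatom bonds can be forbidden", {
  at <- atom_specs(c("C1", "C2"), "C", c(3L, 3L))
  withr <- enumerate_constitutions("C2H8N2", at)
  without <- enumerate_constitutions(
    "C2H8N2", at, config = generation_config(forbid_hetero_hetero = TRUE)
  )
  expect_true(all(without$keys %in% withr$keys))
  has_nn <- function(m) {
    any(m$atoms$element[m$bonds$i] != "C" & m$atoms$element[m$bonds$j] != "C")
  }
  expect_true(any(vapply(withr$constitutions, has_nn, logical(1))))
  expect_false(any(vapply(without$constitutions, has_nn, logical(1))))
})

test_that("candidate set tidiers expose SMILES and run metadata", {
  at <- atom_specs(c("C1", "C2"), "C", c(3L, 2L), "sp3")
  res <- enumerate_constitutions("C2H6O", at)
  td <- tidy(res)
  expect_identical(td$smiles, "CCO")
  gl <- glance(res)
  expect_identical(gl$n_constitutions, 1L)
  expect_false(gl$truncated)
})
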