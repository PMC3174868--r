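ethane <- function() {
  constitution(
    atoms = data.frame(id = c("C1", "C2"), element = "C", n_h = 3L),
    bonds = data.frame(i = 1, j = 2, order = 1)
  )
}

test_that("forward model reproduces the textbook correlation sets", {
  corr <- forward_correlations(
    ethane(), forward_config(c("cosy", "hmbc", "adequate11"))
  )
  expect_identical(nrow(corr$cosy), 1L)
  expect_setequal(c(corr$cosy$a, corr$cosy$b), c("C1", "C2"))
  # HMBC sees both directions on a 2-carbon molecule
  expect_identical(nrow(corr$hmbc), 2L)
  expect_identical(nrow(corr$adequate11), 1L)
  # benzene: 6 ring adjacencies in COSY
  bz <- forward_correlations(benzene(), forward_config("cosy"))
  expect_identical(nrow(bz$cosy), 6L)
  expect_identical(nrow(bz$hmbc), 0L)
})

test_that("forward correlations are always satisfied by their source", {
  for (m in make_toy_structures(808, 8, c(2, 6))) {
    for (exps in list("cosy", c("cosy", "hmbc"),
                      c("cosy", "hmbc", "n15hmbc", "adequate11"))) {
      prob <- toy_problem(m, exps)
      expect_true(isTRUE(check_satisfies(m, prob$constraints)))
    }
  }
})

test_that("dropout removes correlations reproducibly and monotonically", {
  m <- make_toy_structures(99, 1, c(6, 6))[[1]]
  full <- forward_correlations(m, forward_config(c("cosy", "hmbc")))
  d1 <- forward_correlations(m, forward_config(c("cosy", "hmbc"),
                                               dropout = 0.5, seed = 7))
  d2 <- forward_correlations(m, forward_config(c("cosy", "hmbc"),
                                               dropout = 0.5, seed = 7))
  expect_identical(d1$cosy, d2$cosy)
  expect_identical(d1$hmbc, d2$hmbc)
  n_of <- function(cs) nrow(cs$cosy) + nrow(cs$hmbc)
  expect_lte(n_of(d1), n_of(full))
  pair_strings <- function(tb) paste(tb$a, tb$b)
  expect_true(all(pair_strings(d1$hmbc) %in% pair_strings(full$hmbc)))
})

test_that("with dropout the candidate set can only grow", {
  m <- make_toy_structures(111, 1, c(4, 5))[[1]]
  specs <- as_atom_specs(m)
  f <- constitution_formula(m)
  full <- enumerate_constitutions(f, specs, compile_constraints(
    forward_correlations(m, forward_config(c("cosy", "hmbc"))), specs))
  sparse <- enumerate_constitutions(f, specs, compile_constraints(
    forward_correlations(m, forward_config(c("cosy", "hmbc"), dropout = 0.6,
                                           seed = 3)), specs))
  expect_true(all(full$keys %in% sparse$keys))
  expect_true(canonical_key(m) %in% sparse$keys)
})

test_that("toy structures honour their contract", {
  toys <- make_toy_structures(1, 5, c(2, 4))
  expect_length(toys, 5L)
  for (m in toys) {
    expect_silent(validate_constitution(m))
    expect_lte(nrow(m$atoms), 4L)
    expect_gte(nrow(m$atoms), 2L)
    expect_true(any(m$atoms$element == "C" & m$atoms$n_h >= 1L))
  }
  keys <- vapply(toys, canonical_key, character(1))
  expect_identical(length(unique(keys)), 5L)
  # determinism per seed, difference across seeds
  again <- make_toy_structures(1, 5, c(2, 4))
  expect_identical(vapply(again, canonical_key, character(1)), keys)
  other <- make_toy_structures(2, 5, c(2, 4))
  expect_false(identical(vapply(other, canonical_key, character(1)), keys))
})

test_that("toy generation rejects ranges beyond the oracle limit", {
  expect_error(make_toy_structures(1, 2, c(2, 9)),
               class = "nmrcase_input_error")
})

test_that("reference corpora are valid, seeded and usable downstream", {
  expect_error(make_reference_corpus(7, 0), class = "nmrcase_input_error")
  corp <- make_reference_corpus(7, 30)
  expect_length(corp, 30L)
  for (m in corp[1:5]) expect_silent(validate_constitution(m))
  ref <- build_reference(corp)
  expect_gte(nrow(ref), 1L)
  corp2 <- make_reference_corpus(7, 30)
  expect_identical(vapply(corp2, canonical_key, character(1)),
                   vapply(corp, canonical_key, character(1)))
})

test_that("simulated inputs round-trip through the JSON dialect", {
  m <- make_toy_structures(12, 1, c(3, 5))[[1]]
  corr <- forward_correlations(m, forward_config(c("cosy", "hmbc")))
  specs <- as_atom_specs(m)
  path <- withr::local_tempfile(fileext = ".json")
  write_nmr_input(constitution_formula(m), specs, corr, path)
  inp <- read_nmr_input(path)
  expect_identical(format_formula(inp$formula),
                   format_formula(constitution_formula(m)))
  expect_identical(inp$atoms$id, specs$id)
  expect_identical(inp$atoms$n_h, specs$n_h)
  expect_identical(inp$correlations$cosy, corr$cosy)
  expect_identical(inp$correlations$hmbc, corr$hmbc)
})
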