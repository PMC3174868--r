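test_that("one-sphere keys reflect center, H count and neighbor multiset", {
  # methane: no neighbors at all
  expect_identical(env_key(methane(), 1L), "CH4()")
  # ethanol oxygen: one single-bonded carbon neighbor
  eth <- ethanol()
  expect_identical(env_key(eth, 3L), "OH1(C:1)")
  # methyl carbons of ethanol vs dimethyl ether differ by the neighbor element
  dme <- dimethyl_ether()
  expect_identical(env_key(eth, 1L), "CH3(C:1)")
  expect_identical(env_key(dme, 1L), "CH3(O:1)")
  expect_false(env_key(eth, 1L) == env_key(dme, 1L))
})

test_that("neighbor multisets sort by element, then bond order", {
  # C bonded to O (double), O (single), C (single): acetate-like carbon
  m <- constitution(
    atoms = data.frame(element = c("C", "C", "O", "O"),
                       n_h = c(3L, 0L, 0L, 1L)),
    bonds = data.frame(i = c(1, 2, 2), j = c(2, 3, 4), order = c(1, 2, 1))
  )
  expect_identical(env_key(m, 2L), "CH0(C:1,O:1,O:2)")
})

test_that("keys are radius-1 local: distant edits do not change them", {
  for (m in make_toy_structures(404, 5, c(4, 6))) {
    prof <- env_profile(m)
    adj <- nmrcase:::adjacency_list(nrow(m$atoms), m$bonds)
    # graft an extra H -> replace an H on an atom >= 2 bonds from atom 1 by CH3
    far <- setdiff(which(vapply(seq_len(nrow(m$atoms)), function(v) {
      v != 1L && !(v %in% adj[[1L]])
    }, logical(1))), 1L)
    far <- far[m$atoms$n_h[far] > 0L]
    if (length(far) == 0L) next
    v <- far[1]
    m2 <- m
    m2$atoms <- rbind(m$atoms,
                      tibble::tibble(id = "Cnew", element = "C", charge = 0L,
                                     n_h = 3L))
    m2$atoms$n_h[v] <- m2$atoms$n_h[v] - 1L
    m2$bonds <- rbind(m$bonds,
                      tibble::tibble(i = v, j = nrow(m2$atoms), order = 1L))
    m2 <- constitution(m2$atoms, m2$bonds)
    expect_identical(env_profile(m2)[1L], prof[1L])
  }
})

test_that("Kekule forms of a benzenoid ring share one environment profile", {
  expect_identical(sort(env_profile(benzene())),
                   sort(env_profile(benzene(TRUE))))
  expect_identical(env_profile(benzene())[1], "CH1(C:a,C:a)")
})

test_that("reference building counts every atom of every molecule", {
  ref1 <- build_reference(list(methane()))
  expect_identical(nrow(ref1), 1L)
  expect_identical(ref1$count, 1L)
  ref2 <- build_reference(list(methane(), methane()))
  expect_identical(ref2$count, 2L)
  # ethanol has exactly three distinct environments, one atom each
  ref3 <- build_reference(list(ethanol()))
  expect_identical(nrow(ref3), 3L)
  expect_setequal(ref3$env_key, c("CH3(C:1)", "CH2(C:1,O:1)", "OH1(C:1)"))
  expect_identical(ref3$count, c(1L, 1L, 1L))
  meta <- attr(ref3, "meta")
  expect_identical(meta$n_molecules, 1L)
  expect_identical(meta$n_atoms, 3L)
})

test_that("an empty corpus is refused", {
  expect_error(build_reference(list()), class = "nmrcase_input_error")
})

test_that("filtering keeps exactly the covered candidates", {
  ref <- build_reference(list(ethanol()))
  report <- filter_candidates(list(ethanol(), dimethyl_ether()), ref)
  expect_length(report$kept, 1L)
  expect_identical(canonical_key(report$kept[[1]]), canonical_key(ethanol()))
  expect_identical(nrow(report$removed), 1L)
  expect_setequal(report$removed$missing[[1]], c("CH3(O:1)", "OH0(C:1,C:1)"))
  expect_equal(report$reduction, 0.5)
})

test_that("filtering a set against its own reference removes nothing", {
  cands <- make_toy_structures(505, 8, c(2, 6))
  ref <- build_reference(cands)
  report <- filter_candidates(cands, ref)
  expect_length(report$kept, length(cands))
  expect_identical(nrow(report$removed), 0L)
  expect_equal(report$reduction, 0)
})

test_that("filtering is monotone in the corpus and idempotent", {
  cands <- make_toy_structures(606, 10, c(2, 6))
  corpus_small <- make_reference_corpus(607, 15)
  corpus_big <- c(corpus_small, make_reference_corpus(608, 25))
  ref_small <- build_reference(corpus_small)
  ref_big <- build_reference(corpus_big)
  kept_small <- filter_candidates(cands, ref_small)$kept
  kept_big <- filter_candidates(cands, ref_big)$kept
  key_of <- function(ms) vapply(ms, canonical_key, character(1))
  expect_true(all(key_of(kept_small) %in% key_of(kept_big)))
  # idempotence: refiltering the kept set removes nothing
  again <- filter_candidates(kept_small, ref_small)
  expect_length(again$kept, length(kept_small))
  expect_identical(nrow(again$removed), 0L)
})

test_that("a structure whose environments are covered is never removed", {
  toys <- make_toy_structures(709, 10, c(2, 6))
  for (k in seq_along(toys)) {
    m <- toys[[k]]
    corpus <- c(make_reference_corpus(709 + k, 10), list(m))
    ref <- build_reference(corpus)
    report <- filter_candidates(list(m), ref)
    expect_length(report$kept, 1L)
  }
})

test_that("min_count raises the bar for rare environments", {
  cands <- list(ethanol(), dimethyl_ether())
  ref <- build_reference(list(ethanol(), ethanol(), dimethyl_ether()))
  lax <- filter_candidates(cands, ref, min_count = 1L)
  strict <- filter_candidates(cands, ref, min_count = 2L)
  expect_length(lax$kept, 2L)
  expect_length(strict$kept, 1L)
})

test_that("missing-key summary sorts by count then key", {
  report <- filter_candidates(
    list(dimethyl_ether(), dimethyl_ether(), ethanol()),
    build_reference(list(propane()))
  )
  tab <- summarize_missing(report)
  expect_identical(names(tab), c("env_key", "n_candidates"))
  expect_true(all(diff(tab$n_candidates) <= 0))
  ties <- split(tab$env_key, tab$n_candidates)
  for (grp in ties) expect_identical(grp, sort(grp))
  # dimethyl ether contributes its two missing keys twice
  expect_identical(tab$n_candidates[tab$env_key == "CH3(O:1)"], 2L)
  # empty removed list gives an empty table
  empty <- filter_candidates(list(propane()),
                             build_reference(list(propane())))
  expect_identical(nrow(summarize_missing(empty)), 0L)
})

test_that("reference dictionaries round-trip through TSV", {
  ref <- build_reference(make_reference_corpus(42, 20), "toy corpus")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_reference(ref, path)
  back <- read_reference(path)
  expect_identical(back$env_key, ref$env_key)
  expect_identical(back$count, ref$count)
  expect_identical(attr(back, "meta")$n_molecules, 20L)
})

test_that("filter report tidiers and plot summarise the outcome", {
  report <- filter_candidates(list(ethanol(), dimethyl_ether()),
                              build_reference(list(ethanol())))
  td <- tidy(report)
  expect_identical(nrow(td), 2L)
  expect_setequal(td$status, c("kept", "removed"))
  gl <- glance(report)
  expect_identical(gl$n_kept, 1L)
  expect_identical(gl$n_removed, 1L)
  expect_equal(gl$reduction, 0.5)
  p <- autoplot(report)
  expect_s3_class(p, "ggplot")
})
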