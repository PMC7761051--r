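test_that("triplet construction, I/O round-trip and validation", {
  m <- activity_matrix(c("c1", "c1", "c2"), c("t1", "t2", "t1"), c(1, 0, 1))
  expect_equal(sort(compounds(m)), c("c1", "c2"))
  expect_equal(sort(targets(m)), c("t1", "t2"))
  expect_equal(n_outcomes(m), 3)
  expect_equal(outcome_of(m, "c1", "t2"), "inactive")
  expect_equal(outcome_of(m, "c2", "t2"), "untested")

  # conflicting duplicate -> hard error naming the pair
  expect_error(activity_matrix(c("c1", "c1"), c("t1", "t1"), c(1, 0)),
               class = "promdiag_conflict_error")
  # agreeing duplicate collapses silently
  m2 <- activity_matrix(c("c1", "c1"), c("t1", "t1"), c(1, 1))
  expect_equal(n_outcomes(m2), 1)

  # file round-trip preserves the pair -> outcome map exactly
  path <- withr::local_tempfile(fileext = ".tsv")
  write_activity_triplets(toy_matrix(), path)
  back <- read_activity_triplets(path)
  expect_equal(as.matrix(back$m), as.matrix(toy_matrix()$m))

  # empty body with valid header -> empty matrix
  writeLines("compound_id\ttarget_id\toutcome", path)
  empty <- read_activity_triplets(path)
  expect_length(compounds(empty), 0)

  # malformed outcome token -> error with line number
  writeLines(c("compound_id\ttarget_id\toutcome", "c1\tt1\tmaybe"), path)
  expect_error(read_activity_triplets(path), "line 2",
               class = "promdiag_io_error")
})

test_that("promiscuity degree and test frequency", {
  m <- toy_matrix()
  expect_equal(promiscuity_degree(m, "m1"), 3)
  expect_equal(promiscuity_degree(m, "s1"), 1)
  expect_equal(promiscuity_degree(m, "b1"), 0)  # only inactives
  expect_equal(test_frequency(m, "b1"), 2)
  expect_equal(test_frequency(m, "m1"), 3)
  expect_error(promiscuity_degree(m, "nope"),
               class = "promdiag_lookup_error")
  expect_error(test_frequency(m, "nope"), class = "promdiag_lookup_error")

  # property: PD <= TF <= |targets| on random matrices, via exhaustive
  # recount from outcome_of()
  for (seed in 1:25) {
    rm <- random_matrix(seed = seed)
    pd <- promiscuity_degree(rm); tf <- test_frequency(rm)
    expect_true(all(pd <= tf))
    expect_true(all(tf <= length(targets(rm))))
    for (cp in head(compounds(rm), 3)) {
      oc <- vapply(targets(rm), function(t) outcome_of(rm, cp, t),
                   character(1))
      expect_equal(unname(pd[cp]), sum(oc == "active"))
      expect_equal(unname(tf[cp]), sum(oc != "untested"))
    }
  }
})

test_that("assay hit-rate filtering", {
  cps <- sprintf("c%03d", 1:100)
  m <- activity_matrix(
    rep(cps, 2), rep(c("hot", "cold"), each = 100),
    c(rep(1, 3), rep(0, 97),    # hot: 3% hit rate
      rep(1, 1), rep(0, 99))    # cold: 1%
  )
  f <- filter_assays(m, assay_filter_config(max_hit_rate = 0.02))
  expect_equal(targets(f), "cold")
  # idempotent
  f2 <- filter_assays(f, assay_filter_config(max_hit_rate = 0.02))
  expect_equal(as.matrix(f2$m), as.matrix(f$m))
  # everything above threshold -> empty matrix
  all_hot <- activity_matrix(cps[1:10], rep("t", 10), rep(1, 10))
  expect_length(targets(filter_assays(all_hot)), 0)
  expect_error(assay_filter_config(max_hit_rate = 0),
               class = "promdiag_config_error")
})

test_that("flagged-compound removal counts the union once", {
  cps <- sprintf("c%02d", 1:10)
  m <- activity_matrix(rep(cps, each = 2),
                       rep(c("t1", "t2"), 10),
                       rep(c(1, 0), 10))
  flags <- data.frame(
    compound_id = c("c01", "c02", "c03", "c03"),
    flag = c("PAINS", "PAINS", "PAINS", "FLUC")
  )
  lib <- compound_library(cps, flags = flags)
  res <- remove_flagged_compounds(m, lib)
  expect_equal(res$report$original, 10)
  expect_equal(unname(res$report$removed_per_flag["PAINS"]), 3)
  expect_equal(unname(res$report$removed_per_flag["FLUC"]), 1)
  expect_equal(res$report$removed_total, 3)   # c03 counted once
  expect_equal(res$report$final, 7)
  expect_equal(length(compounds(res$matrix)), 7)
  # outcomes of survivors unchanged
  expect_equal(outcome_of(res$matrix, "c04", "t2"), "inactive")
  expect_equal(outcome_of(res$matrix, "c05", "t1"), "active")

  # no flags -> identity
  res0 <- remove_flagged_compounds(m, compound_library(cps))
  expect_equal(as.matrix(res0$matrix$m), as.matrix(m$m))
  expect_equal(res0$report$final, 10)

  # missing record -> hard error
  expect_error(remove_flagged_compounds(m, compound_library(cps[1:5])),
               class = "promdiag_lookup_error")
})

test_that("compound library I/O (.smi + flags TSV)", {
  smi <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("c1ccccc1 benz", "Cc1ccccc1 tolu"), smi)
  fl <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("compound_id\tflag", "benz\tPAINS"), fl)
  lib <- read_compound_library(smi, fl)
  expect_equal(lib$records$id, c("benz", "tolu"))
  expect_equal(lib$records$smiles[1], "c1ccccc1")
  expect_equal(lib$flags$flag, "PAINS")
  expect_error(compound_library(c("a", "a")),
               class = "promdiag_config_error")
  expect_error(
    compound_library("a", flags = data.frame(compound_id = "a",
                                             flag = "WEIRD")),
    class = "promdiag_config_error")
})
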