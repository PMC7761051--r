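test_that("MT-CPD identification honors the PD threshold", {
  m <- toy_matrix()
  expect_equal(identify_mt_compounds(m, group_sampling_config(3)), "m1")
  expect_equal(identify_mt_compounds(m, group_sampling_config(2)),
               c("m1", "s3"))
  empty <- random_matrix(density = 0)
  expect_length(identify_mt_compounds(empty, group_sampling_config(2)), 0)
  expect_error(group_sampling_config(1), class = "promdiag_config_error")
})

test_that("ST sampling enforces eligibility and the omission rule", {
  m <- toy_matrix()
  cfg <- group_sampling_config(pd_threshold = 3, rng_seed = 1)
  g <- sample_st_group(m, "m1", cfg)
  # brute-force eligibility on the toy matrix: only s1 qualifies (s2 is
  # untested on t3, s3 has PD 2, b1 is never active)
  expect_equal(g$targets, c("t1", "t2", "t3"))
  expect_equal(g$st, c(t1 = "s1"))
  expect_true(verify_completeness(g, m))

  # below-threshold precondition
  expect_error(sample_st_group(m, "s1", cfg),
               class = "promdiag_precondition_error")

  # no eligible candidate anywhere -> NULL (group omitted)
  m2 <- activity_matrix(c("m1", "m1", "m1", "z1"),
                        c("t1", "t2", "t3", "t1"),
                        c(1, 1, 1, 1))  # z1 untested on t2/t3
  expect_null(sample_st_group(m2, "m1", cfg))

  # seeded reproducibility with two interchangeable candidates
  m3 <- activity_matrix(
    c("m1", "m1", "m1", "a", "a", "a", "b", "b", "b"),
    rep(c("t1", "t2", "t3"), 3),
    c(1, 1, 1, 1, 0, 0, 1, 0, 0))
  g1 <- sample_st_group(m3, "m1", group_sampling_config(3, rng_seed = 7))
  g2 <- sample_st_group(m3, "m1", group_sampling_config(3, rng_seed = 7))
  expect_identical(g1, g2)
  picks <- vapply(1:40, function(s)
    sample_st_group(m3, "m1", group_sampling_config(3, rng_seed = s))$st[["t1"]],
    character(1))
  expect_setequal(unique(picks), c("a", "b"))  # both candidates reachable
})

test_that("build_groups matches brute-force counting and is reproducible", {
  # independent exhaustive scan for the expected group count
  brute_count <- function(m, thr) {
    pd <- promiscuity_degree(m)
    mts <- names(pd)[pd >= thr]
    sum(vapply(mts, function(mt) {
      tg <- targets(m)[vapply(targets(m), function(t)
        outcome_of(m, mt, t) == "active", logical(1))]
      any(vapply(tg, function(t) {
        others <- setdiff(tg, t)
        any(vapply(setdiff(compounds(m), mt), function(c) {
          pd[[c]] == 1 && outcome_of(m, c, t) == "active" &&
            all(vapply(others, function(o)
              outcome_of(m, c, o) == "inactive", logical(1)))
        }, logical(1)))
      }, logical(1)))
    }, logical(1)))
  }
  for (seed in 1:10) {
    m <- random_matrix(n_compounds = 14, n_targets = 5, density = 0.7,
                       seed = seed)
    g2 <- build_groups(m, group_sampling_config(2, rng_seed = 1))
    expect_equal(length(g2), brute_count(m, 2))
    g3 <- build_groups(m, group_sampling_config(3, rng_seed = 1))
    expect_equal(length(g3), brute_count(m, 3))
    expect_gte(length(g2), length(g3))  # monotone in threshold
    expect_true(all(vapply(g2, verify_completeness, logical(1), x = m)))
    # no duplicate ST inside one group
    for (g in g2) expect_false(anyDuplicated(unname(g$st)) > 0)
  }
  # bit-reproducibility under a fixed seed
  m <- random_matrix(n_compounds = 20, n_targets = 6, density = 0.7,
                     seed = 99)
  expect_identical(build_groups(m, group_sampling_config(2, rng_seed = 5)),
                   build_groups(m, group_sampling_config(2, rng_seed = 5)))
})

test_that("verify_completeness rejects broken groups", {
  m <- toy_matrix()
  g <- sample_st_group(m, "m1", group_sampling_config(3, rng_seed = 1))
  expect_true(verify_completeness(g, m))
  # ST untested on one group target
  g_bad <- make_group("m1", c("t1", "t2", "t3"), c(t2 = "s2"))
  expect_false(verify_completeness(g_bad, m))
  # ST active on two group targets
  g_bad2 <- make_group("m1", c("t1", "t2", "t3"), c(t3 = "s3"))
  expect_false(verify_completeness(g_bad2, m))
})

test_that("groups serialize to JSON Lines and back", {
  m <- toy_matrix()
  g <- build_groups(m, group_sampling_config(3, rng_seed = 1))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_groups(g, path)
  back <- read_groups(path)
  expect_equal(length(back), length(g))
  expect_equal(back[[1]]$mt, g[[1]]$mt)
  expect_equal(back[[1]]$st, g[[1]]$st)
  expect_equal(back[[1]]$targets, g[[1]]$targets)
})
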