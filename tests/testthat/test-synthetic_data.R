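test_that("library generation: counts, similarity structure, determinism", {
  cfg <- sim_config(n_targets = 40, n_series = 4, series_size = 5,
                    n_singletons = 10, promiscuity_signal = 1,
                    label_noise = 0, rng_seed = 3)
  lib <- simulate_library(cfg)
  # 2 families: 2x5 MT members + 2x5x5 ST members + 10 singletons
  expect_equal(nrow(lib$fps), 10 + 50 + 10)
  expect_identical(simulate_library(cfg)$fps, lib$fps)  # seed-stable

  truth <- lib$truth
  mt_ids <- truth$id[truth$planted == "MT"]
  expect_length(mt_ids, 10)
  expect_length(truth$id[truth$planted == "ST"], 50)

  # within-series similarity far above between-series, with clear bands
  within <- c(); between <- c()
  s1 <- truth$id[!is.na(truth$series) & truth$series == 1]
  s3 <- truth$id[!is.na(truth$series) & truth$series == 3]
  K <- tanimoto_kernel(fp_subset(lib$fps, c(s1, s3)))
  n1 <- length(s1)
  within <- c(K[1:n1, 1:n1][upper.tri(diag(n1))],
              K[-(1:n1), -(1:n1)][upper.tri(diag(length(s3)))])
  between <- K[1:n1, -(1:n1)]
  expect_gt(mean(within), 0.5)
  expect_lt(mean(between), 0.2)
})

test_that("activity planting: recovery, completeness, test frequencies", {
  cfg <- sim_config(n_series = 10, series_size = 5, n_singletons = 150,
                    promiscuity_signal = 1, label_noise = 0, rng_seed = 9)
  lib <- simulate_library(cfg)
  mat <- simulate_activity(lib, cfg)

  # planted MT-CPDs have PD >= pd_mt and are recovered as complete groups
  truth <- lib$truth
  planted_mt <- truth$id[truth$planted == "MT"]
  pd <- promiscuity_degree(mat)
  expect_true(all(pd[planted_mt] >= cfg$pd_mt))
  groups <- build_groups(mat, group_sampling_config(5, rng_seed = 2))
  rec <- mean(planted_mt %in% vapply(groups, `[[`, character(1), "mt"))
  expect_gte(rec, 0.95)
  expect_true(all(vapply(groups, verify_completeness, logical(1),
                         x = mat)))

  # median test frequency within +-20% of the target
  tf <- test_frequency(mat)
  expect_lt(abs(median(tf) - cfg$test_frequency_target),
            0.2 * cfg$test_frequency_target)

  # infeasible pd exceeds target count
  expect_error(sim_config(n_targets = 3, pd_mt = 5),
               class = "promdiag_config_error")
  expect_error(sim_config(core_bits_per_series = 2000,
                          substituent_bits_per_compound = 200),
               class = "promdiag_config_error")
})

test_that("benchmark bundles are self-describing, reproducible, curatable", {
  cfg <- sim_config(n_targets = 40, n_series = 4, series_size = 4,
                    n_singletons = 40, test_frequency_target = 20,
                    rng_seed = 17)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  b1 <- generate_benchmark(cfg, d1, flag_fraction = 0.1)
  b2 <- generate_benchmark(cfg, d2, flag_fraction = 0.1)
  for (f in c("activity.tsv", "fingerprints.tsv", "flags.tsv",
              "ground_truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  manifest <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(manifest$rng_seed, 17)
  expect_equal(manifest$flag_fraction, 0.1)

  # the curation stage removes exactly the flagged compounds
  mat <- read_activity_triplets(file.path(d1, "activity.tsv"))
  flags <- read.delim(file.path(d1, "flags.tsv"),
                      colClasses = "character")
  lib <- compound_library(compounds(mat), flags = flags)
  res <- remove_flagged_compounds(mat, lib)
  expect_setequal(setdiff(compounds(mat), compounds(res$matrix)),
                  unique(flags$compound_id))
})

test_that("all-singleton world has no analogs and no planted groups", {
  cfg <- sim_config(n_targets = 40, n_series = 0, series_size = 1,
                    n_singletons = 30, test_frequency_target = 15,
                    rng_seed = 4)
  lib <- simulate_library(cfg)
  expect_equal(nrow(lib$fps), 30)
  expect_true(all(lib$truth$planted == "background"))
  keys <- setNames(lapply(lib$truth$series, function(s)
    if (is.na(s)) character(0) else as.character(s)), lib$truth$id)
  expect_equal(analog_fraction(cores = keys), 0)
  mat <- simulate_activity(lib, cfg)
  expect_length(build_groups(mat, group_sampling_config(5, 1)), 0)
})
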