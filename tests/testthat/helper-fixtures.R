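# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# The canonical toy matrix: one MT-CPD (m1, active on t1..t3), eligible and
# ineligible ST candidates, and a background compound.
toy_matrix <- function() {
  rows <- list(
    c("m1", "t1", 1), c("m1", "t2", 1), c("m1", "t3", 1),
    # s1: perfect ST candidate for t1
    c("s1", "t1", 1), c("s1", "t2", 0), c("s1", "t3", 0),
    # s2: active t2 but untested on t3 -> ineligible
    c("s2", "t2", 1), c("s2", "t1", 0),
    # s3: PD 2 -> ineligible
    c("s3", "t3", 1), c("s3", "t1", 1), c("s3", "t2", 0),
    # b1: inactive everywhere
    c("b1", "t1", 0), c("b1", "t2", 0)
  )
  m <- do.call(rbind, rows)
  activity_matrix(m[, 1], m[, 2], as.integer(m[, 3]))
}

# Random ternary matrix with outcome density `density` and hit rate ~0.3.
random_matrix <- function(n_compounds = 12, n_targets = 6, density = 0.5,
                          seed = 1) {
  set.seed(seed)
  grid <- expand.grid(c = sprintf("c%02d", seq_len(n_compounds)),
                      t = sprintf("t%02d", seq_len(n_targets)),
                      stringsAsFactors = FALSE)
  keep <- runif(nrow(grid)) < density
  grid <- grid[keep, , drop = FALSE]
  if (!nrow(grid)) grid <- data.frame(c = "c01", t = "t01")[0, ]
  activity_matrix(grid$c, grid$t,
                  as.integer(runif(nrow(grid)) < 0.3))
}

# Random fingerprint set: n compounds, popcount ~ bits_on of n_bits.
random_fps <- function(n = 10, n_bits = 64, bits_on = 16, seed = 1,
                       ids = sprintf("c%02d", seq_len(n))) {
  set.seed(seed)
  m <- t(vapply(seq_len(n), function(i) {
    v <- integer(n_bits); v[sample(n_bits, bits_on)] <- 1L
    v
  }, integer(n_bits)))
  rownames(m) <- ids
  fingerprint_set(m)
}

# Hand-built groups over explicit fingerprints, for condition/ML tests.
make_group <- function(mt, targets, st) {
  structure(list(mt = mt, targets = targets, st = st), class = "MTGroup")
}

# A small planted benchmark (few seconds): returns groups + fps + matrix.
small_benchmark <- function(seed = 1, s = 0.9, n_series = 12,
                            series_size = 4, label_noise = 0.01) {
  cfg <- sim_config(n_targets = 80, n_series = n_series,
                    series_size = series_size, n_singletons = 150,
                    test_frequency_target = 30,
                    promiscuity_signal = s, label_noise = label_noise,
                    rng_seed = seed)
  lib <- simulate_library(cfg)
  mat <- simulate_activity(lib, cfg)
  groups <- build_groups(mat, group_sampling_config(5, rng_seed = seed))
  list(cfg = cfg, lib = lib, mat = mat, groups = groups)
}

# Independent metric oracle: rebuild label vectors from counts and use
# generic statistics (class-wise accuracy means, harmonic mean, Pearson
# correlation for MCC) rather than the closed-form confusion expressions.
oracle_metrics <- function(TP, TN, FP, FN) {
  truth <- c(rep(1, TP + FN), rep(0, TN + FP))
  pred <- c(rep(1, TP), rep(0, FN), rep(0, TN), rep(1, FP))
  prec <- if (sum(pred) == 0) 0 else mean(truth[pred == 1])
  rec <- mean(pred[truth == 1])
  mcc <- suppressWarnings(stats::cor(truth, pred))
  list(
    BA = (mean(pred[truth == 1] == 1) + mean(pred[truth == 0] == 0)) / 2,
    F1 = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec),
    MCC = if (is.na(mcc)) 0 else mcc,
    precision = prec,
    recall = rec
  )
}

# O(n^2) AUC oracle: concordant-pair counting with ties at 1/2.
oracle_auc <- function(labels, scores) {
  pos <- which(labels == "MT"); neg <- which(labels == "ST")
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

# Exhaustive KNN oracle: per-pair tanimoto(), full sort, majority vote.
oracle_knn <- function(train_fps, train_labels, test_fps, k) {
  train_ids <- rownames(train_fps)
  vapply(seq_len(nrow(test_fps)), function(i) {
    d <- vapply(seq_len(nrow(train_fps)), function(j)
      1 - tanimoto(test_fps[i, ], train_fps[j, ]), numeric(1))
    o <- order(d, train_ids)[seq_len(k)]
    frac <- mean(train_labels[train_ids[o]] == "MT")
    if (frac > 0.5) "MT" else "ST"
  }, character(1))
}
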