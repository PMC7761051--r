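test_that("balancing draws one ST per group, uniformly over trials", {
  groups <- list(
    make_group("m1", c("t1", "t2"), c(t1 = "a", t2 = "b")),
    make_group("m2", c("t1", "t3"), c(t1 = "c"))
  )
  p <- balance_groups(groups, seed = 1)
  expect_equal(nrow(p), 2)
  expect_equal(p$mt, c("m1", "m2"))
  expect_equal(p$st[2], "c")            # single candidate always chosen
  draws <- vapply(1:200, function(s) balance_groups(groups, s)$st[1],
                  character(1))
  frac_a <- mean(draws == "a")
  expect_gt(frac_a, 0.4); expect_lt(frac_a, 0.6)  # ~1/2 each
})

test_that("pair-level splits keep partners together and sizes exact", {
  pairs <- data.frame(mt = sprintf("m%03d", 1:100),
                      st = sprintf("s%03d", 1:100))
  sp <- split_pairs(pairs, 0.2, seed = 4)
  expect_equal(nrow(sp$train), 80)
  expect_equal(nrow(sp$test), 20)
  expect_length(intersect(c(sp$train$mt, sp$train$st),
                          c(sp$test$mt, sp$test$st)), 0)
  sp50 <- split_pairs(pairs, 0.5, seed = 4)
  expect_equal(nrow(sp50$train), 50)
  expect_equal(nrow(sp50$test), 50)
  expect_error(split_pairs(pairs[1:3, ], 0.2),
               class = "promdiag_precondition_error")
})

test_that("knn classification matches definitions and the exhaustive oracle", {
  # hand case: k=3, nearest labels MT, MT, ST -> MT with score 2/3
  m <- rbind(q = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L))
  train <- rbind(
    n1 = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L),   # sim 1 (MT)
    n2 = c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L),   # sim .75 (MT)
    n3 = c(1L, 1L, 0L, 0L, 1L, 0L, 0L, 0L),   # sim .4 (ST)
    n4 = c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L)    # sim 0 (ST)
  )
  labels <- c(n1 = "MT", n2 = "MT", n3 = "ST", n4 = "ST")
  res <- knn_classify(fingerprint_set(train), labels,
                      fingerprint_set(m), k = 3)
  expect_equal(res$pred, "MT")
  expect_equal(res$score, 2 / 3)
  # k=1 on an exact duplicate
  res1 <- knn_classify(fingerprint_set(train), labels,
                       fingerprint_set(m), k = 1)
  expect_equal(res1$pred, "MT")
  expect_error(knn_classify(fingerprint_set(train), labels,
                            fingerprint_set(m), k = 5),
               class = "promdiag_precondition_error")

  # oracle equivalence on random draws, and invariance to training order
  for (seed in 1:20) {
    fps <- random_fps(24, n_bits = 48, bits_on = 12, seed = seed)
    train_fps <- fp_subset(fps, 1:16)
    test_fps <- fp_subset(fps, 17:24)
    labels <- setNames(rep(c("MT", "ST"), 8), rownames(train_fps))
    for (k in c(1, 3, 5)) {
      got <- knn_classify(train_fps, labels, test_fps, k)
      expect_equal(got$pred, oracle_knn(train_fps, labels, test_fps, k))
      shuf <- sample(16)
      got2 <- knn_classify(fp_subset(train_fps, shuf), labels[shuf],
                           test_fps, k)
      expect_equal(got2$pred, got$pred)
    }
  }
})

test_that("confusion counts and the metric equations", {
  cc <- confusion(rep(c("MT", "ST"), each = 5), rep(c("MT", "ST"), each = 5))
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]),
               c(TP = 5, TN = 5, FP = 0, FN = 0))
  m <- compute_metrics(cc)
  expect_equal(unlist(m), c(BA = 1, F1 = 1, MCC = 1, precision = 1,
                            recall = 1))
  inv <- confusion(rep(c("MT", "ST"), each = 5),
                   rep(c("ST", "MT"), each = 5))
  expect_equal(compute_metrics(inv)$MCC, -1)
  expect_error(confusion("MT", "yes"), class = "promdiag_label_error")

  # hand-evaluated example: TP=4, FP=1, TN=3, FN=2
  cc2 <- structure(list(TP = 4, TN = 3, FP = 1, FN = 2),
                   class = "ConfusionCounts")
  m2 <- compute_metrics(cc2)
  expect_equal(m2$precision, 0.8)
  expect_equal(m2$recall, 2 / 3, tolerance = 1e-12)
  expect_equal(m2$F1, 8 / 11, tolerance = 1e-12)
  expect_equal(m2$BA, (2 / 3 + 3 / 4) / 2, tolerance = 1e-12)
  expect_equal(m2$MCC, 10 / sqrt(600), tolerance = 1e-12)

  # all-positive predictor on balanced data: BA 0.5, MCC 0 by convention
  ap <- confusion(rep(c("MT", "ST"), each = 4), rep("MT", 8))
  map <- compute_metrics(ap)
  expect_equal(map$BA, 0.5)
  expect_equal(map$MCC, 0)
  expect_error(compute_metrics(structure(list(TP = 0, TN = 0, FP = 0,
                                              FN = 0),
                                         class = "ConfusionCounts")),
               class = "promdiag_metric_error")
})

test_that("roc_auc: printed anchors and the concordant-pair oracle", {
  labs <- rep(c("MT", "ST"), each = 10)
  expect_equal(roc_auc(labs, c(rep(1, 10), rep(0, 10))), 1)    # perfect
  expect_equal(roc_auc(labs, rep(0.3, 20)), 0.5)               # constant
  expect_error(roc_auc(rep("MT", 5), runif(5)),
               class = "promdiag_class_error")
  set.seed(42)
  for (i in 1:50) {
    n <- sample(6:20, 1)
    labs <- sample(rep(c("MT", "ST"), length.out = n))
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force ties
    expect_equal(roc_auc(labs, scores), oracle_auc(labs, scores),
                 tolerance = 1e-12)
  }
  pts <- roc_points(rep(c("MT", "ST"), each = 3), c(3, 2, 1, 2, 1, 0))
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[nrow(pts)], 1)
})

test_that("tanimoto kernel Gram matrices are valid SVM kernels", {
  for (seed in 1:10) {
    fps <- random_fps(15, n_bits = 64, bits_on = sample(5:30, 1),
                      seed = seed)
    K <- tanimoto_kernel(fps)
    expect_equal(unname(diag(K)), rep(1, 15))
    expect_equal(K, t(K))
    expect_gte(min(eigen(K, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-8)
  }
})

test_that("double CV runs all three models on a small benchmark", {
  bench <- small_benchmark(seed = 3)
  expect_gte(length(bench$groups), 10)
  prot <- cv_protocol(n_external_trials = 3, n_internal_trials = 2)
  fps <- bench$lib$fps

  res_knn <- run_double_cv(bench$groups, fps, "KNN", protocol = prot,
                           seed = 5)
  expect_equal(nrow(res_knn), 3)
  expect_true(all(res_knn$BA >= 0 & res_knn$BA <= 1))
  expect_true(all(res_knn$TP + res_knn$TN + res_knn$FP + res_knn$FN ==
                    res_knn$TP[1] + res_knn$TN[1] + res_knn$FP[1] +
                    res_knn$FN[1]))
  # reproducible under the same master seed
  res_knn2 <- run_double_cv(bench$groups, fps, "KNN", protocol = prot,
                            seed = 5)
  expect_equal(res_knn$BA, res_knn2$BA)
  expect_s3_class(attr(res_knn, "roc_first_trial"), "data.frame")

  res_rf <- run_double_cv(bench$groups, fps, "RF",
                          rf_config(10, c(2, 5)), prot, seed = 5)
  expect_equal(nrow(res_rf), 3)
  expect_true(all(res_rf$AUC >= 0 & res_rf$AUC <= 1))

  res_svm <- run_double_cv(bench$groups, fps, "SVM",
                           svm_config(c(1, 10)), prot, seed = 5)
  expect_equal(nrow(res_svm), 3)
  expect_true(all(grepl("kernel=", res_svm$params)))

  # with strong signal all models clearly beat chance
  expect_gt(mean(res_knn$BA), 0.6)
  expect_gt(mean(res_rf$BA), 0.6)
  expect_gt(mean(res_svm$BA), 0.6)

  sm <- summary(res_knn)
  expect_true(all(c("BA_mean", "BA_sd", "MCC_mean") %in% names(sm)))
  expect_error(run_double_cv(bench$groups[1:5], fps, "KNN"),
               class = "promdiag_precondition_error")
})
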