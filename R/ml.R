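#' Cross-validation protocol
#'
#' Double cross-validation: in each external trial the dataset is balanced
#' (one ST-CPD drawn per group), split at the pair level into training and
#' test sets, and the hyper-parameter grid is scored by internal trials on
#' sub-splits of the training pairs; the best grid point (by mean internal
#' balanced accuracy) is refit on the full training set and evaluated on
#' the held-out test pairs.
#'
#' @param n_external_trials number of independent external trials
#'   (default 10).
#' @param test_fraction external test share (default 0.2; 0.5 is the
#'   stability control).
#' @param n_internal_trials internal trials for model selection
#'   (default 10).
#' @param internal_test_fraction internal validation share (default 0.2).
#' @return a `CVProtocol`.
#' @export
cv_protocol <- function(n_external_trials = 10, test_fraction = 0.2,
                        n_internal_trials = 10,
                        internal_test_fraction = 0.2) {
  fr <- c(test_fraction, internal_test_fraction)
  if (any(fr <= 0 | fr >= 1)) {
    pd_stop("fractions must lie in (0,1)", "promdiag_config_error")
  }
  if (n_external_trials < 1 || n_internal_trials < 1) {
    pd_stop("trial counts must be >= 1", "promdiag_config_error")
  }
  structure(list(n_external_trials = as.integer(n_external_trials),
                 test_fraction = test_fraction,
                 n_internal_trials = as.integer(n_internal_trials),
                 internal_test_fraction = internal_test_fraction),
            class = "CVProtocol")
}

#' Model hyper-parameter grids
#'
#' Defaults follow the standard diagnostic setup: KNN with k in {1,3,5};
#' random forest over n_estimators {10,100,250,500} x min_samples_split
#' {2,3,5,7,10}; SVM over C in {0.1,1,10,50,100,200,400,500,750,1000} with
#' the linear and Tanimoto kernels both in the grid (the inner loop picks
#' the kernel as well). Ties in the inner loop resolve toward the more
#' parsimonious grid point (smaller k / fewer trees / smaller C, linear
#' before Tanimoto).
#'
#' @param k_grid odd positive neighbor counts.
#' @return model config object.
#' @export
knn_config <- function(k_grid = c(1, 3, 5)) {
  if (any(k_grid %% 2 != 1 | k_grid < 1)) {
    pd_stop("k values must be odd and positive", "promdiag_config_error")
  }
  structure(list(k_grid = sort(as.integer(k_grid))), class = "KNNConfig")
}

#' @rdname knn_config
#' @param n_estimators_grid,min_samples_split_grid RF grids.
#' @export
rf_config <- function(n_estimators_grid = c(10, 100, 250, 500),
                      min_samples_split_grid = c(2, 3, 5, 7, 10)) {
  if (!length(n_estimators_grid) || !length(min_samples_split_grid)) {
    pd_stop("grids must be non-empty", "promdiag_config_error")
  }
  structure(list(n_estimators_grid = sort(as.integer(n_estimators_grid)),
                 min_samples_split_grid =
                   sort(as.integer(min_samples_split_grid))),
            class = "RFConfig")
}

#' @rdname knn_config
#' @param c_grid SVM regularization values (all > 0).
#' @param kernels subset of `c("linear", "tanimoto")`.
#' @export
svm_config <- function(c_grid = c(0.1, 1, 10, 50, 100, 200, 400, 500, 750,
                                  1000),
                       kernels = c("linear", "tanimoto")) {
  if (any(c_grid <= 0)) pd_stop("C values must be > 0",
                                "promdiag_config_error")
  kernels <- match.arg(kernels, several.ok = TRUE)
  structure(list(c_grid = sort(c_grid), kernels = kernels),
            class = "SVMConfig")
}

default_model_config <- function(model) {
  switch(model, KNN = knn_config(), RF = rf_config(), SVM = svm_config())
}

# Grid points in parsimony order (first = preferred on ties).
model_grid <- function(model, config) {
  switch(model,
    KNN = lapply(config$k_grid, function(k) list(k = k)),
    RF = {
      g <- expand.grid(min_samples_split = config$min_samples_split_grid,
                       n_estimators = config$n_estimators_grid)
      g <- g[order(g$n_estimators, g$min_samples_split), ]
      lapply(seq_len(nrow(g)), function(i)
        list(n_estimators = g$n_estimators[i],
             min_samples_split = g$min_samples_split[i]))
    },
    SVM = {
      out <- list()
      for (C in config$c_grid) for (kern in config$kernels) {
        out[[length(out) + 1]] <- list(C = C, kernel = kern)
      }
      out
    }
  )
}

format_params <- function(params) {
  paste(sprintf("%s=%s", names(params),
                vapply(params, function(v) as.character(v), character(1))),
        collapse = ",")
}

#' Balance groups into MT/ST pairs
#'
#' Draws exactly one ST-CPD uniformly at random from each group, yielding a
#' dataset with equal numbers of MT and ST instances.
#'
#' @param groups list of `MTGroup`.
#' @param seed integer seed.
#' @return data.frame with columns `mt`, `st`, one row per group.
#' @export
balance_groups <- function(groups, seed = 1L) {
  with_seed(seed, {
    st <- vapply(groups, function(g) {
      s <- unname(g$st)
      s[sample.int(length(s), 1)]
    }, character(1))
  })
  data.frame(mt = vapply(groups, `[[`, character(1), "mt"), st = st)
}

#' Split MT/ST pairs into training and test sets
#'
#' The split happens at the pair level: an MT-CPD and its matched ST-CPD
#' always land in the same partition, so no compound (nor its matched
#' partner) leaks between training and test.
#'
#' @param pairs data.frame from [balance_groups()].
#' @param test_fraction held-out share.
#' @param seed integer seed.
#' @return list with `train` and `test` data.frames.
#' @export
split_pairs <- function(pairs, test_fraction = 0.2, seed = 1L) {
  n <- nrow(pairs)
  n_test <- floor(test_fraction * n)
  if (n_test < 1 || n - n_test < 1) {
    pd_stop(sprintf("too few pairs (%d) for a %.0f%% test split", n,
                    100 * test_fraction), "promdiag_precondition_error")
  }
  idx <- with_seed(seed, sample.int(n, n_test))
  list(train = pairs[-idx, , drop = FALSE],
       test = pairs[idx, , drop = FALSE])
}

#' k-nearest-neighbor classification with Tanimoto distance
#'
#' Training compounds are ranked nearest-first by fingerprint distance
#' (1 - Tanimoto); the majority class among the k nearest carries the
#' prediction, and the MT fraction among those k neighbors is the score.
#' Distance ties are broken by lexicographic compound identifier so
#' predictions do not depend on training-set order.
#'
#' @param train_fps,test_fps `FingerprintSet`s.
#' @param train_labels named vector of `"MT"`/`"ST"` for the training rows.
#' @param k odd neighbor count, at most `nrow(train_fps)`.
#' @return data.frame with `id`, `pred`, `score`.
#' @export
knn_classify <- function(train_fps, train_labels, test_fps, k) {
  if (k > nrow(train_fps)) {
    pd_stop("k exceeds the training set size", "promdiag_precondition_error")
  }
  sim <- tanimoto_kernel(test_fps, train_fps)
  res <- knn_from_sim(sim, train_labels[rownames(train_fps)] == "MT", k)
  data.frame(id = rownames(test_fps),
             pred = ifelse(res$pred == 1, "MT", "ST"),
             score = res$score, row.names = NULL)
}

# Core KNN on a precomputed similarity block (rows = test, cols = train).
# y_train is logical (TRUE = MT). Ties in distance resolve by column
# (training id) order, so callers must pass columns sorted by identifier.
knn_from_sim <- function(sim, y_train, k) {
  ord_names <- order(colnames(sim))
  sim <- sim[, ord_names, drop = FALSE]
  y <- y_train[ord_names]
  pred <- integer(nrow(sim)); score <- numeric(nrow(sim))
  for (i in seq_len(nrow(sim))) {
    o <- order(-sim[i, ])[seq_len(k)]   # stable: ties keep id order
    frac <- mean(y[o])
    pred[i] <- as.integer(frac > 0.5)
    score[i] <- frac
  }
  list(pred = pred, score = score)
}

#' Confusion counts
#'
#' MT is the positive class.
#'
#' @param true_labels,predicted_labels equal-length vectors of `"MT"`/`"ST"`.
#' @return a `ConfusionCounts` list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) {
    pd_stop("label vectors differ in length", "promdiag_precondition_error")
  }
  if (!all(c(true_labels, predicted_labels) %in% c("MT", "ST"))) {
    pd_stop("labels must be MT or ST", "promdiag_label_error")
  }
  t_pos <- true_labels == "MT"; p_pos <- predicted_labels == "MT"
  structure(list(TP = sum(t_pos & p_pos), TN = sum(!t_pos & !p_pos),
                 FP = sum(!t_pos & p_pos), FN = sum(t_pos & !p_pos)),
            class = "ConfusionCounts")
}

#' Performance measures from confusion counts
#'
#' Balanced accuracy BA = (TPR + TNR) / 2; Matthews correlation
#' coefficient (0 by convention when any marginal is zero);
#' F1 = 2 TP / (2 TP + FP + FN); precision = TP / (TP + FP);
#' recall = TP / (TP + FN).
#'
#' @param cc a [confusion()] result.
#' @return a `MetricSet` list: `BA`, `F1`, `MCC`, `precision`, `recall`.
#' @export
compute_metrics <- function(cc) {
  n <- cc$TP + cc$TN + cc$FP + cc$FN
  if (n == 0) pd_stop("empty confusion", "promdiag_metric_error")
  if (cc$TP + cc$FN == 0 || cc$TN + cc$FP == 0) {
    pd_stop("balanced accuracy needs both classes present",
            "promdiag_metric_error")
  }
  tpr <- cc$TP / (cc$TP + cc$FN)
  tnr <- cc$TN / (cc$TN + cc$FP)
  marg <- c(cc$TP + cc$FP, cc$TP + cc$FN, cc$TN + cc$FP, cc$TN + cc$FN)
  mcc <- if (any(marg == 0)) 0 else {
    (cc$TP * cc$TN - cc$FP * cc$FN) / sqrt(prod(marg))
  }
  structure(list(
    BA = (tpr + tnr) / 2,
    F1 = if (2 * cc$TP + cc$FP + cc$FN == 0) 0
         else 2 * cc$TP / (2 * cc$TP + cc$FP + cc$FN),
    MCC = mcc,
    precision = if (cc$TP + cc$FP == 0) 0 else cc$TP / (cc$TP + cc$FP),
    recall = tpr
  ), class = "MetricSet")
}

#' ROC area under the curve
#'
#' Rank-statistic AUC with midrank tie handling: the probability that a
#' random MT instance scores above a random ST instance, ties counted 1/2.
#'
#' @param true_labels `"MT"`/`"ST"` vector.
#' @param scores numeric scores, larger = more MT-like.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(true_labels, scores) {
  pos <- true_labels == "MT"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    pd_stop("AUC needs both classes", "promdiag_class_error")
  }
  r <- rank(scores)   # midranks for ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return data.frame of `fpr`, `tpr` swept over score thresholds.
#' @export
roc_points <- function(true_labels, scores) {
  o <- order(-scores)
  pos <- (true_labels == "MT")[o]
  tpr <- cumsum(pos) / sum(pos)
  fpr <- cumsum(!pos) / sum(!pos)
  keep <- !duplicated(scores[o], fromLast = TRUE)  # one point per threshold
  data.frame(fpr = c(0, fpr[keep]), tpr = c(0, tpr[keep]))
}
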