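#' Double cross-validation for diagnostic models
#'
#' Runs the complete diagnostic protocol for one model on one set of
#' MT-/ST-CPD groups: per external trial, balance the groups into MT/ST
#' pairs, split at the pair level, select the hyper-parameter grid point
#' (and for SVM, the kernel) with the best mean internal balanced accuracy,
#' refit on the full training pairs, and evaluate on the held-out pairs.
#' KNN and the Tanimoto kernel are computed in R; RF and SVM fits are
#' delegated to scikit-learn through the bundled worker, operating on data
#' matrices and Gram matrices prepared here.
#'
#' @param groups list of `MTGroup` (at least 10).
#' @param fps `FingerprintSet` covering every group member.
#' @param model `"KNN"`, `"RF"` or `"SVM"`.
#' @param config model grid config ([knn_config()], [rf_config()],
#'   [svm_config()]); defaults to the standard grid.
#' @param protocol a [cv_protocol()].
#' @param seed master seed; all per-trial randomness derives from it.
#' @return data.frame of per-trial results (class `promdiag_cv`): chosen
#'   hyper-parameters, confusion counts, BA/F1/MCC/precision/recall, AUC.
#'   The ROC points of the first trial are attached as
#'   `attr(, "roc_first_trial")`.
#' @export
run_double_cv <- function(groups, fps, model = c("KNN", "RF", "SVM"),
                          config = NULL, protocol = cv_protocol(),
                          seed = 1L) {
  model <- match.arg(model)
  if (length(groups) < 10) {
    pd_stop("need at least 10 groups", "promdiag_precondition_error")
  }
  config <- config %||% default_model_config(model)
  grid <- model_grid(model, config)

  # Instance universe: all compounds that can appear in any trial.
  used <- sort(unique(c(vapply(groups, `[[`, character(1), "mt"),
                        unlist(lapply(groups, function(g) unname(g$st))))))
  ufps <- fp_subset(fps, used)
  y <- setNames(used %in% vapply(groups, `[[`, character(1), "mt"), used)

  need_kernel <- model == "KNN" ||
    (model == "SVM" && "tanimoto" %in% vapply(grid, `[[`, character(1),
                                              "kernel"))
  K <- if (need_kernel) tanimoto_kernel(ufps) else NULL

  # Build every fit task up front so the backend is called once.
  tasks <- list()
  trials <- vector("list", protocol$n_external_trials)
  for (t in seq_len(protocol$n_external_trials)) {
    pairs <- balance_groups(groups, derive_seed(seed, t * 31L))
    sp <- split_pairs(pairs, protocol$test_fraction,
                      derive_seed(seed, t * 31L + 1L))
    inner <- lapply(seq_len(protocol$n_internal_trials), function(i) {
      split_pairs(sp$train, protocol$internal_test_fraction,
                  derive_seed(seed, t * 1009L + i))
    })
    trials[[t]] <- list(split = sp, inner = inner)
    for (g in seq_along(grid)) {
      for (i in seq_len(protocol$n_internal_trials)) {
        tasks[[length(tasks) + 1]] <- list(
          id = sprintf("t%d_g%d_i%d", t, g, i),
          params = grid[[g]],
          train = pair_instances(inner[[i]]$train, used),
          test = pair_instances(inner[[i]]$test, used),
          seed = derive_seed(seed, t * 7919L + g * 97L + i))
      }
      tasks[[length(tasks) + 1]] <- list(
        id = sprintf("t%d_g%d_final", t, g),
        params = grid[[g]],
        train = pair_instances(sp$train, used),
        test = pair_instances(sp$test, used),
        seed = derive_seed(seed, t * 7919L + g * 97L))
    }
  }

  preds <- execute_tasks(model, tasks, ufps, y, K)

  rows <- list(); roc_first <- NULL
  for (t in seq_len(protocol$n_external_trials)) {
    mean_ba <- vapply(seq_along(grid), function(g) {
      bas <- vapply(seq_len(protocol$n_internal_trials), function(i) {
        p <- preds[[sprintf("t%d_g%d_i%d", t, g, i)]]
        ids <- pair_instances(trials[[t]]$inner[[i]]$test, used)
        internal_ba(y[ids], p$pred)
      }, numeric(1))
      mean(bas, na.rm = TRUE)
    }, numeric(1))
    g_star <- which.max(mean_ba)   # first max = parsimony tie-break
    p <- preds[[sprintf("t%d_g%d_final", t, g_star)]]
    ids <- pair_instances(trials[[t]]$split$test, used)
    truth <- ifelse(y[ids], "MT", "ST")
    predicted <- ifelse(p$pred == 1, "MT", "ST")
    cc <- confusion(truth, predicted)
    met <- compute_metrics(cc)
    auc <- roc_auc(truth, p$score)
    if (t == 1) roc_first <- roc_points(truth, p$score)
    rows[[t]] <- data.frame(
      model = model, trial = t, params = format_params(grid[[g_star]]),
      internal_BA = mean_ba[g_star],
      TP = cc$TP, TN = cc$TN, FP = cc$FP, FN = cc$FN,
      BA = met$BA, F1 = met$F1, MCC = met$MCC,
      precision = met$precision, recall = met$recall, AUC = auc)
  }
  out <- do.call(rbind, rows)
  attr(out, "roc_first_trial") <- roc_first
  class(out) <- c("promdiag_cv", "data.frame")
  out
}

# Instances of a pair table, as positions into the id universe
# (MT instances first, then the matched ST instances).
pair_instances <- function(pairs, used) {
  match(c(pairs$mt, pairs$st), used)
}

# Balanced accuracy from logical truth and 0/1 predictions; NA when the
# validation slice is single-class (degenerate split, recorded and skipped).
internal_ba <- function(truth, pred01) {
  pos <- truth; neg <- !truth
  if (!any(pos) || !any(neg)) return(NA_real_)
  (mean(pred01[pos] == 1) + mean(pred01[neg] == 0)) / 2
}

# Run every fit task: KNN locally, RF/SVM through the sklearn worker.
execute_tasks <- function(model, tasks, ufps, y, K) {
  if (model == "KNN") {
    out <- lapply(tasks, function(task) {
      sim <- K[task$test, task$train, drop = FALSE]
      colnames(sim) <- rownames(ufps)[task$train]
      knn_from_sim(sim, setNames(y[task$train], colnames(sim)), task$params$k)
    })
    names(out) <- vapply(tasks, `[[`, character(1), "id")
    return(out)
  }
  sidecars <- list(X.txt = apply(unclass(ufps), 1, paste0, collapse = ""))
  if (!is.null(K)) {
    sidecars$K.txt <- apply(K, 1, function(r) paste(sprintf("%.8f", r),
                                                    collapse = " "))
  }
  payload <- list(
    model = tolower(model),
    labels = as.integer(y),
    tasks = lapply(tasks, function(task) {
      list(id = task$id, params = task$params,
           kernel = task$params$kernel %||% "linear",
           train = task$train, test = task$test, seed = task$seed)
    })
  )
  res <- run_py_worker("sklearn_worker.py", payload, sidecars)
  out <- list()
  for (i in seq_len(nrow(res$results))) {
    out[[res$results$id[i]]] <- list(pred = res$results$pred[[i]],
                                     score = res$results$score[[i]])
  }
  out
}

#' Summarize per-trial CV results
#'
#' @param object a `promdiag_cv` data.frame (or an rbind of several).
#' @param ... unused.
#' @return data.frame of mean and sd per measure, by model (and any
#'   `condition` column present).
#' @export
summary.promdiag_cv <- function(object, ...) {
  by_cols <- intersect(c("condition", "model"), names(object))
  measures <- c("BA", "F1", "MCC", "precision", "recall", "AUC")
  split_keys <- interaction(object[by_cols], drop = TRUE)
  rows <- lapply(split(object, split_keys), function(d) {
    out <- d[1, by_cols, drop = FALSE]
    for (m in measures) {
      out[[paste0(m, "_mean")]] <- mean(d[[m]])
      out[[paste0(m, "_sd")]] <- sd(d[[m]])
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
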