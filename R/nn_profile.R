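#' Nearest-neighbor similarity profile
#'
#' For every compound, computes its largest Tanimoto similarity to any
#' *other* MT-labelled compound and to any other ST-labelled compound
#' (self excluded). The resulting table is the input for the joint-KDE view
#' of nearest-neighbor structure: MT-CPDs lying above the diagonal are
#' closer to another MT-CPD than to any ST-CPD, the asymmetry that drives
#' the diagnostic ML results.
#'
#' @param fps a `FingerprintSet`.
#' @param labels named character vector (`"MT"`/`"ST"`) covering the rows
#'   of `fps`; both classes need at least 2 members.
#' @return data.frame with columns `id`, `label`, `sim_nn_mt`, `sim_nn_st`.
#' @export
nn_profile <- function(fps, labels) {
  ids <- rownames(fps)
  labels <- labels[ids]
  if (any(is.na(labels)) || !all(labels %in% c("MT", "ST"))) {
    pd_stop("labels must cover all compounds with values MT/ST",
            "promdiag_config_error")
  }
  for (cls in c("MT", "ST")) {
    if (sum(labels == cls) < 2) {
      pd_stop(sprintf("class %s has fewer than 2 members", cls),
              "promdiag_class_error")
    }
  }
  sim <- tanimoto_kernel(fps)
  diag(sim) <- -Inf
  mt_cols <- which(labels == "MT")
  st_cols <- which(labels == "ST")
  data.frame(
    id = ids,
    label = unname(labels),
    sim_nn_mt = apply(sim[, mt_cols, drop = FALSE], 1, max),
    sim_nn_st = apply(sim[, st_cols, drop = FALSE], 1, max),
    row.names = NULL
  )
}

#' Export a nearest-neighbor profile as TSV
#'
#' Columns `id`, `label`, `sim_nn_mt`, `sim_nn_st`; the file is the direct
#' input for 2D kernel-density plots of NN structure.
#'
#' @param profile output of [nn_profile()].
#' @param path output file.
#' @export
export_nn_table <- function(profile, path) {
  write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Labels implied by a set of groups: the MT compound of any group is MT,
# every sampled ST compound is ST.
group_labels <- function(groups) {
  mt <- unique(vapply(groups, `[[`, character(1), "mt"))
  st <- unique(unlist(lapply(groups, function(g) unname(g$st))))
  setNames(c(rep("MT", length(mt)), rep("ST", length(st))), c(mt, st))
}
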