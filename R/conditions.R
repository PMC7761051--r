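#' Dataset condition configuration
#'
#' The diagnostic design compares three conditions: the full set of
#' MT-/ST-CPD groups, a 50% random removal of groups (size control), and a
#' 50% nearest-neighbor removal in which the 25% of groups whose MT-CPDs
#' are most similar to other groups' MT-CPDs and the 25% whose ST-CPDs are
#' most similar to other groups' ST-CPDs are discarded.
#'
#' @param condition `"FULL"`, `"RANDOM_REMOVAL"` or `"NN_REMOVAL"`.
#' @param removal_fraction net fraction of groups removed (default 0.5).
#' @param nn_fraction_mt,nn_fraction_st MT-side and ST-side shares of the
#'   NN removal; they must sum to `removal_fraction`.
#' @param st_aggregate how a group's ST-side score aggregates over its
#'   ST-CPDs: `"max"` (nearest relationship, default) or `"mean"`.
#' @param rng_seed seed for the random-removal draw.
#' @return a `ConditionConfig`.
#' @export
condition_config <- function(condition = c("FULL", "RANDOM_REMOVAL",
                                           "NN_REMOVAL"),
                             removal_fraction = 0.5,
                             nn_fraction_mt = 0.25, nn_fraction_st = 0.25,
                             st_aggregate = c("max", "mean"),
                             rng_seed = 1L) {
  condition <- match.arg(condition)
  st_aggregate <- match.arg(st_aggregate)
  fr <- c(removal_fraction, nn_fraction_mt, nn_fraction_st)
  if (any(fr < 0 | fr > 1)) {
    pd_stop("fractions must lie in [0, 1]", "promdiag_config_error")
  }
  if (abs(nn_fraction_mt + nn_fraction_st - removal_fraction) > 1e-9) {
    pd_stop("nn_fraction_mt + nn_fraction_st must equal removal_fraction",
            "promdiag_config_error")
  }
  structure(list(condition = condition,
                 removal_fraction = removal_fraction,
                 nn_fraction_mt = nn_fraction_mt,
                 nn_fraction_st = nn_fraction_st,
                 st_aggregate = st_aggregate,
                 rng_seed = as.integer(rng_seed)),
            class = "ConditionConfig")
}

#' Random group removal
#'
#' Removes `floor(removal_fraction * n)` groups uniformly at random -- the
#' size-matched control for NN removal.
#'
#' @param groups list of `MTGroup`.
#' @param config a [condition_config()].
#' @return surviving groups (input order preserved).
#' @export
random_removal <- function(groups, config = condition_config("RANDOM_REMOVAL")) {
  n <- length(groups)
  if (n < 2) pd_stop("need at least 2 groups", "promdiag_precondition_error")
  k <- floor(config$removal_fraction * n)
  if (k >= n) pd_stop("removal fraction would remove every group",
                      "promdiag_config_error")
  if (k == 0) return(groups)
  drop <- with_seed(config$rng_seed, sample.int(n, k))
  groups[-drop]
}

# Group-level NN scores. MT side: similarity of the group's MT-CPD to the
# nearest MT-CPD of any other group. ST side: aggregate (max or mean) over
# the group's ST-CPDs of similarity to the nearest ST-CPD outside the
# group (shared compound ids excluded).
mt_side_scores <- function(groups, fps) {
  mt_ids <- vapply(groups, `[[`, character(1), "mt")
  sim <- tanimoto_kernel(fp_subset(fps, mt_ids))
  diag(sim) <- -Inf
  apply(sim, 1, max)
}

st_side_scores <- function(groups, fps, aggregate = "max") {
  st_ids <- unique(unlist(lapply(groups, function(g) unname(g$st))))
  sim <- tanimoto_kernel(fp_subset(fps, st_ids))
  diag(sim) <- -Inf
  vapply(groups, function(g) {
    own <- unname(g$st)
    outside <- setdiff(st_ids, own)
    if (!length(outside)) return(-Inf)
    nn <- apply(sim[own, outside, drop = FALSE], 1, max)
    if (aggregate == "mean") mean(nn) else max(nn)
  }, numeric(1))
}

#' Nearest-neighbor group removal
#'
#' Two-pass ablation: first the `nn_fraction_mt` share of groups whose
#' MT-CPDs have the highest similarity to another group's MT-CPD is
#' removed; then, among the survivors, the groups whose ST-CPDs are most
#' similar to ST-CPDs outside the group are removed until the net cut
#' reaches `removal_fraction` of the original count. The two passes are
#' disjoint by construction and the output size matches [random_removal()]
#' at equal fractions. Ties are broken by MT-CPD identifier.
#'
#' @param groups list of `MTGroup` (at least 4).
#' @param fps `FingerprintSet` covering all group members.
#' @param config a [condition_config()].
#' @return list with `groups` (survivors) and `manifest` (data.frame of
#'   removed groups: `mt`, `side`, `score`).
#' @export
nn_removal <- function(groups, fps,
                       config = condition_config("NN_REMOVAL")) {
  n <- length(groups)
  if (n < 4) pd_stop("need at least 4 groups", "promdiag_precondition_error")
  k_total <- floor(config$removal_fraction * n)
  k_mt <- floor(config$nn_fraction_mt * n)
  k_st <- k_total - k_mt
  if (k_total >= n || k_st > n - k_mt) {
    pd_stop("insufficient groups for the requested removal fractions",
            "promdiag_config_error")
  }
  mt_ids <- vapply(groups, `[[`, character(1), "mt")

  s_mt <- mt_side_scores(groups, fps)
  ord <- order(-s_mt, mt_ids)
  drop_mt <- ord[seq_len(k_mt)]
  survivors <- setdiff(seq_len(n), drop_mt)

  s_st <- st_side_scores(groups[survivors], fps, config$st_aggregate)
  ord2 <- order(-s_st, mt_ids[survivors])
  drop_st <- survivors[ord2[seq_len(k_st)]]

  keep <- setdiff(seq_len(n), c(drop_mt, drop_st))
  manifest <- data.frame(
    mt = c(mt_ids[drop_mt], mt_ids[drop_st]),
    side = c(rep("MT", length(drop_mt)), rep("ST", length(drop_st))),
    score = c(s_mt[drop_mt], s_st[match(drop_st, survivors)])
  )
  list(groups = groups[keep], manifest = manifest)
}

#' Apply a dataset condition
#'
#' Dispatches on `config$condition`: identity for `FULL`, otherwise the
#' corresponding removal.
#'
#' @inheritParams nn_removal
#' @return list with `groups` and (for NN removal) `manifest`.
#' @export
apply_condition <- function(groups, fps, config) {
  switch(config$condition,
    FULL = list(groups = groups, manifest = NULL),
    RANDOM_REMOVAL = list(groups = random_removal(groups, config),
                          manifest = NULL),
    NN_REMOVAL = nn_removal(groups, fps, config)
  )
}
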