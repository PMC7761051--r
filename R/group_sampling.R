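#' Group sampling configuration
#'
#' @param pd_threshold minimum promiscuity degree for a compound to count
#'   as multi-target (MT-CPD). The two thresholds used in practice are 5
#'   (mixed and biochemical assays) and 3 (biochemical assays); any value
#'   >= 2 is accepted.
#' @param rng_seed integer seed controlling the random choice among
#'   eligible ST-CPD candidates.
#' @return a `GroupSamplingConfig`.
#' @export
group_sampling_config <- function(pd_threshold = 5, rng_seed = 1L) {
  if (pd_threshold < 2) {
    pd_stop("pd_threshold must be >= 2 (multi-target means several targets)",
            "promdiag_config_error")
  }
  structure(list(pd_threshold = as.integer(pd_threshold),
                 rng_seed = as.integer(rng_seed)),
            class = "GroupSamplingConfig")
}

#' Identify multi-target compounds
#'
#' @param x a curated `ActivityMatrix`.
#' @param config a [group_sampling_config()].
#' @return identifiers of all compounds with PD >= threshold, sorted.
#' @export
identify_mt_compounds <- function(x, config = group_sampling_config()) {
  pd <- promiscuity_degree(x)
  sort(names(pd)[pd >= config$pd_threshold])
}

# Internal: eligible ST-CPD candidates for one target of an MT group.
# A candidate must have global PD = 1, be ACTIVE on `tgt`, and be
# explicitly INACTIVE (not merely untested) on every other group target.
st_candidates <- function(x, tgt, other_targets, pd) {
  sub <- x$m[, c(tgt, other_targets), drop = FALSE]
  ok_active <- sub[, 1] > 0
  ok_inactive <- if (length(other_targets)) {
    Matrix::rowSums(sub[, -1, drop = FALSE] < 0) == length(other_targets)
  } else rep(TRUE, nrow(sub))
  ids <- rownames(sub)[ok_active & ok_inactive]
  ids[pd[ids] == 1]
}

#' Sample the matched single-target group for one MT-CPD
#'
#' For each target the MT-CPD is active against, one single-target compound
#' (PD = 1) active on that target but *explicitly inactive* on every other
#' group target is drawn uniformly at random from the eligible candidates,
#' if any exist. Untested never qualifies as inactive: the whole point of
#' the grouping is data completeness, so every group member carries a
#' recorded outcome for every group target. When no target has an eligible
#' candidate the MT-CPD is omitted and `NULL` is returned.
#'
#' @param x an `ActivityMatrix`.
#' @param mt an MT-CPD identifier with PD >= `config$pd_threshold`.
#' @param config a [group_sampling_config()].
#' @return an `MTGroup` (fields `mt`, `targets`, `st`: named vector
#'   target -> ST-CPD id), or `NULL` when every candidate set is empty.
#' @export
sample_st_group <- function(x, mt, config = group_sampling_config(),
                            pd = NULL) {
  pd <- pd %||% promiscuity_degree(x)
  if (!mt %in% names(pd)) {
    pd_stop(sprintf("unknown compound '%s'", mt), "promdiag_lookup_error")
  }
  if (pd[[mt]] < config$pd_threshold) {
    pd_stop(sprintf("'%s' has PD below the MT threshold %d", mt,
                    config$pd_threshold),
            "promdiag_precondition_error")
  }
  row <- x$m[mt, ]
  group_targets <- sort(colnames(x$m)[as.numeric(row) > 0])
  st <- character(0)
  with_seed(derive_seed(config$rng_seed,
                        sum(utf8ToInt(mt)) + length(group_targets)), {
    for (tgt in group_targets) {
      cand <- st_candidates(x, tgt, setdiff(group_targets, tgt), pd)
      cand <- setdiff(cand, c(mt, st))
      if (length(cand)) {
        st[tgt] <- sort(cand)[sample.int(length(cand), 1)]
      }
    }
  })
  if (!length(st)) return(NULL)
  structure(list(mt = mt, targets = group_targets, st = st),
            class = "MTGroup")
}

#' @export
print.MTGroup <- function(x, ...) {
  cat(sprintf("MTGroup: %s on {%s}; %d matched ST-CPDs\n",
              x$mt, paste(x$targets, collapse = ", "), length(x$st)))
  invisible(x)
}

#' Build all MT-/ST-CPD groups
#'
#' Iterates MT-CPDs in sorted identifier order (so the seeded sampling is
#' independent of input file ordering) and keeps every group with at least
#' one matched ST-CPD.
#'
#' @param x a curated `ActivityMatrix`.
#' @param config a [group_sampling_config()].
#' @return list of `MTGroup` objects.
#' @export
build_groups <- function(x, config = group_sampling_config()) {
  mts <- identify_mt_compounds(x, config)
  pd <- promiscuity_degree(x)
  groups <- lapply(mts, function(mt) sample_st_group(x, mt, config, pd))
  Filter(Negate(is.null), groups)
}

#' Verify data completeness of a group
#'
#' Checks the contract every emitted group must satisfy: the MT-CPD is
#' active on all group targets; each ST-CPD is active on exactly its own
#' key target and explicitly inactive on the remaining group targets; and
#' every member has a recorded outcome for every group target.
#'
#' @param group an `MTGroup`.
#' @param x the `ActivityMatrix` it was sampled from.
#' @return `TRUE` or `FALSE`.
#' @export
verify_completeness <- function(group, x) {
  tg <- group$targets
  if (!all(tg %in% colnames(x$m))) return(FALSE)
  members <- c(group$mt, unname(group$st))
  if (!all(members %in% rownames(x$m))) return(FALSE)
  sub <- as.matrix(x$m[members, tg, drop = FALSE])
  if (any(sub == 0)) return(FALSE)               # untested cell
  if (any(sub[1, ] <= 0)) return(FALSE)          # MT must be active on all
  for (i in seq_along(group$st)) {
    patt <- sub[i + 1, ]
    key <- names(group$st)[i]
    if (patt[key] <= 0) return(FALSE)
    if (any(patt[setdiff(tg, key)] >= 0)) return(FALSE)
  }
  if (anyDuplicated(unname(group$st))) return(FALSE)
  TRUE
}

#' Serialize groups as JSON Lines
#'
#' One object per line with keys `mt`, `targets`, `st`.
#'
#' @param groups list of `MTGroup`.
#' @param path output file.
#' @export
write_groups <- function(groups, path) {
  lines <- vapply(groups, function(g) {
    jsonlite::toJSON(list(mt = g$mt, targets = g$targets,
                          st = as.list(g$st)),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_groups
#' @export
read_groups <- function(path) {
  lapply(readLines(path, warn = FALSE), function(line) {
    o <- jsonlite::fromJSON(line)
    structure(list(mt = o$mt, targets = o$targets,
                   st = unlist(o$st)), class = "MTGroup")
  })
}
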