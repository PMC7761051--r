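#' Ternary compound-target activity matrices
#'
#' An `ActivityMatrix` stores screening outcomes for compound-target pairs in
#' ternary form: every pair is either ACTIVE, INACTIVE, or absent (untested).
#' Internally outcomes live in a sparse matrix (compounds x targets) with
#' `+1` = active, `-1` = inactive and structural zero = untested, which keeps
#' promiscuity-degree and test-frequency queries O(nnz).
#'
#' @param compound,target character vectors of equal length naming the pairs.
#' @param outcome integer/numeric vector of `1` (active) or `0` (inactive).
#' @return An object of class `ActivityMatrix`.
#' @examples
#' m <- activity_matrix(c("c1", "c1", "c2"), c("t1", "t2", "t1"), c(1, 0, 1))
#' promiscuity_degree(m, "c1")
#' @export
activity_matrix <- function(compound = character(), target = character(),
                            outcome = integer()) {
  stopifnot(length(compound) == length(target),
            length(target) == length(outcome))
  compound <- as.character(compound)
  target <- as.character(target)
  if (!all(outcome %in% c(0, 1))) {
    pd_stop("outcomes must be 1 (active) or 0 (inactive)",
            "promdiag_outcome_error")
  }
  key <- paste(compound, target, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    agree <- vapply(unique(dup), function(k) {
      length(unique(outcome[key == k])) == 1L
    }, logical(1))
    if (!all(agree)) {
      bad <- unique(dup)[!agree][1]
      pd_stop(sprintf("conflicting outcomes for pair (%s)",
                      gsub("\r", ", ", bad, fixed = TRUE)),
              "promdiag_conflict_error")
    }
    keep <- !duplicated(key)
    compound <- compound[keep]; target <- target[keep]
    outcome <- outcome[keep]
  }
  cps <- sort(unique(compound))
  tgs <- sort(unique(target))
  m <- Matrix::sparseMatrix(
    i = match(compound, cps), j = match(target, tgs),
    x = ifelse(outcome == 1, 1, -1),
    dims = c(length(cps), length(tgs)), dimnames = list(cps, tgs)
  )
  structure(list(m = m), class = "ActivityMatrix")
}

#' @export
print.ActivityMatrix <- function(x, ...) {
  cat(sprintf(
    "ActivityMatrix: %d compounds x %d targets, %d outcomes (%d active)\n",
    nrow(x$m), ncol(x$m), Matrix::nnzero(x$m), sum(x$m@x > 0)))
  invisible(x)
}

#' @rdname activity_matrix
#' @param x an `ActivityMatrix`.
#' @export
compounds <- function(x) rownames(x$m)

#' @rdname activity_matrix
#' @export
targets <- function(x) colnames(x$m)

#' @rdname activity_matrix
#' @export
n_outcomes <- function(x) Matrix::nnzero(x$m)

# Internal: dense ternary row for one compound (+1/-1/0).
compound_row <- function(x, compound) {
  i <- match(compound, rownames(x$m))
  if (is.na(i)) {
    pd_stop(sprintf("unknown compound '%s'", compound),
            "promdiag_lookup_error")
  }
  as.numeric(x$m[i, ])
}

#' Outcome of a single compound-target pair
#'
#' @param x an `ActivityMatrix`.
#' @param compound,target identifiers.
#' @return `"active"`, `"inactive"` or `"untested"`.
#' @export
outcome_of <- function(x, compound, target) {
  i <- match(compound, rownames(x$m)); j <- match(target, colnames(x$m))
  if (is.na(i) || is.na(j)) return("untested")
  v <- x$m[i, j]
  if (v > 0) "active" else if (v < 0) "inactive" else "untested"
}

#' Promiscuity degree (PD)
#'
#' The promiscuity degree of a compound is the number of targets it is
#' recorded ACTIVE against. Single-target compounds (ST-CPDs) have PD = 1;
#' multi-target compounds (MT-CPDs) are defined by a PD threshold.
#'
#' @param x an `ActivityMatrix`.
#' @param compound optional identifier; when omitted, PDs for all compounds
#'   are returned as a named vector.
#' @return integer count, or named integer vector.
#' @export
promiscuity_degree <- function(x, compound = NULL) {
  pd <- Matrix::rowSums(x$m > 0)
  if (is.null(compound)) return(pd)
  if (!compound %in% names(pd)) {
    pd_stop(sprintf("unknown compound '%s'", compound),
            "promdiag_lookup_error")
  }
  unname(pd[compound])
}

#' Test frequency
#'
#' Number of targets with any recorded outcome (active or inactive) for a
#' compound, i.e. how extensively the compound was assayed.
#'
#' @inheritParams promiscuity_degree
#' @return integer count, or named integer vector.
#' @export
test_frequency <- function(x, compound = NULL) {
  tf <- Matrix::rowSums(x$m != 0)
  if (is.null(compound)) return(tf)
  if (!compound %in% names(tf)) {
    pd_stop(sprintf("unknown compound '%s'", compound),
            "promdiag_lookup_error")
  }
  unname(tf[compound])
}

#' Read / write activity triplet files
#'
#' The on-disk format is a UTF-8 TSV with header
#' `compound_id<TAB>target_id<TAB>outcome`, one row per tested pair,
#' `outcome` coded `1` = active, `0` = inactive. Untested pairs are absent.
#'
#' @param path file path.
#' @return `read_activity_triplets` returns an `ActivityMatrix`;
#'   `write_activity_triplets` invisibly returns `path`.
#' @export
read_activity_triplets <- function(path) {
  if (!file.exists(path)) {
    pd_stop(sprintf("no such file: %s", path), "promdiag_io_error")
  }
  d <- read.delim(path, header = TRUE, colClasses = "character",
                  quote = "", stringsAsFactors = FALSE)
  if (!identical(names(d)[1:3], c("compound_id", "target_id", "outcome"))) {
    pd_stop("expected header compound_id\ttarget_id\toutcome",
            "promdiag_io_error")
  }
  bad <- which(!d$outcome %in% c("0", "1"))
  if (length(bad)) {
    pd_stop(sprintf("malformed outcome '%s' on line %d",
                    d$outcome[bad[1]], bad[1] + 1L),
            "promdiag_io_error")
  }
  activity_matrix(d$compound_id, d$target_id, as.integer(d$outcome))
}

#' @rdname read_activity_triplets
#' @param x an `ActivityMatrix`.
#' @export
write_activity_triplets <- function(x, path) {
  tri <- Matrix::summary(x$m)
  d <- data.frame(
    compound_id = rownames(x$m)[tri$i],
    target_id = colnames(x$m)[tri$j],
    outcome = ifelse(tri$x > 0, 1L, 0L)
  )
  d <- d[order(d$compound_id, d$target_id), ]
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Internal: subset an ActivityMatrix, dropping empty rows/columns.
subset_matrix <- function(x, keep_compounds = NULL, keep_targets = NULL) {
  m <- x$m
  if (!is.null(keep_compounds)) m <- m[rownames(m) %in% keep_compounds, ,
                                       drop = FALSE]
  if (!is.null(keep_targets)) m <- m[, colnames(m) %in% keep_targets,
                                     drop = FALSE]
  m <- m[Matrix::rowSums(m != 0) > 0, , drop = FALSE]
  m <- m[, Matrix::colSums(m != 0) > 0, drop = FALSE]
  structure(list(m = m), class = "ActivityMatrix")
}
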