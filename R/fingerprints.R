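#' Fingerprint sets
#'
#' A `FingerprintSet` is a dense 0/1 integer matrix, one row per compound
#' (rownames = identifiers), with a fixed number of bit columns (default
#' 2048) and a provider tag recording how the bits were produced
#' (`"morgan_r2"`, `"maccs"`, or `"precomputed"`). All similarity
#' computations in the package operate on this container, so machine
#' learning and nearest-neighbor analysis run identically on RDKit-computed
#' and synthetic fingerprints.
#'
#' @param bits a 0/1 matrix with rownames, or a named character vector of
#'   bitstrings (`"0101..."`, bit 0 leftmost).
#' @param provider provider tag.
#' @return a `FingerprintSet`.
#' @export
fingerprint_set <- function(bits, provider = "precomputed") {
  if (is.character(bits)) {
    ids <- names(bits)
    if (is.null(ids)) pd_stop("bitstrings must be named",
                              "promdiag_config_error")
    n <- unique(nchar(bits))
    if (length(n) != 1) pd_stop("bitstrings have differing lengths",
                                "promdiag_fp_error")
    m <- matrix(0L, length(bits), n, dimnames = list(ids, NULL))
    for (i in seq_along(bits)) {
      m[i, ] <- as.integer(strsplit(bits[[i]], "", fixed = TRUE)[[1]] == "1")
    }
    bits <- m
  }
  bits <- as.matrix(bits)
  if (is.null(rownames(bits))) pd_stop("fingerprint matrix needs rownames",
                                       "promdiag_config_error")
  storage.mode(bits) <- "integer"
  if (length(bits) && !all(bits %in% c(0L, 1L))) {
    pd_stop("fingerprints must be binary", "promdiag_fp_error")
  }
  structure(bits, provider = provider, class = c("FingerprintSet", "matrix"))
}

#' @export
print.FingerprintSet <- function(x, ...) {
  cat(sprintf("FingerprintSet: %d compounds x %d bits (%s)\n",
              nrow(x), ncol(x), attr(x, "provider")))
  invisible(x)
}

#' @rdname fingerprint_set
#' @param x a `FingerprintSet`.
#' @param i row subscript (identifiers or indices).
#' @export
fp_subset <- function(x, i) {
  fingerprint_set(unclass(x)[i, , drop = FALSE],
                  provider = attr(x, "provider"))
}

#' Tanimoto similarity
#'
#' For bit sets a and b, Tc = |a AND b| / |a OR b|. Pairs of all-zero
#' fingerprints are assigned similarity 0 (the 0/0 case), a conservative
#' convention that never inflates nearest-neighbor statistics.
#'
#' @param a,b single fingerprints: 0/1 vectors of equal length (rows of a
#'   `FingerprintSet`).
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) != length(b)) {
    pd_stop("fingerprint lengths differ", "promdiag_fp_error")
  }
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) 0 else inter / uni
}

#' Tanimoto similarity matrix / kernel
#'
#' Computes the Gram matrix of pairwise Tanimoto similarities between two
#' fingerprint sets via bit-count algebra
#' (|a AND b| / (|a| + |b| - |a AND b|)). Used both as the SVM kernel and
#' for all nearest-neighbor profiling.
#'
#' @param A,B `FingerprintSet`s (or 0/1 matrices) with equal bit length.
#'   `B` defaults to `A`.
#' @return a `nrow(A)` x `nrow(B)` matrix of similarities in \[0, 1\].
#' @export
tanimoto_kernel <- function(A, B = A) {
  A <- unclass(as.matrix(A)); B <- unclass(as.matrix(B))
  if (ncol(A) != ncol(B)) {
    pd_stop("fingerprint lengths differ", "promdiag_fp_error")
  }
  storage.mode(A) <- "double"; storage.mode(B) <- "double"
  inter <- A %*% t(B)
  pa <- rowSums(A); pb <- rowSums(B)
  uni <- outer(pa, pb, `+`) - inter
  k <- inter / uni
  k[uni == 0] <- 0
  dimnames(k) <- list(rownames(A), rownames(B))
  k
}

#' Read / write fingerprint files
#'
#' TSV format: `compound_id<TAB>bitstring`, where the bitstring is
#' `n_bits` characters of 0/1, bit index 0 leftmost; header row
#' `compound_id\tfingerprint`.
#'
#' @param path file path.
#' @param provider provider tag attached on read.
#' @return `read_fingerprints` returns a `FingerprintSet`.
#' @export
read_fingerprints <- function(path, provider = "precomputed") {
  d <- read.delim(path, header = TRUE, colClasses = "character", quote = "")
  fingerprint_set(setNames(d[[2]], d[[1]]), provider = provider)
}

#' @rdname read_fingerprints
#' @param fps a `FingerprintSet`.
#' @export
write_fingerprints <- function(fps, path) {
  m <- unclass(fps)
  strs <- apply(m, 1, paste0, collapse = "")
  d <- data.frame(compound_id = rownames(m), fingerprint = strs)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Morgan fingerprints from SMILES (RDKit backend)
#'
#' Computes radius-2 Morgan fingerprints folded to `n_bits` (default 2048)
#' by delegating to RDKit through the bundled Python worker. Requires a
#' `python` with RDKit on the PATH; the precomputed-fingerprint workflow
#' does not need it.
#'
#' @param smiles named character vector (names = compound ids).
#' @param provider `"morgan_r2"` (default) or `"maccs"` (166-bit structural
#'   keys, control representation).
#' @param n_bits fold length for Morgan bits.
#' @return a `FingerprintSet`.
#' @export
compute_fingerprint <- function(smiles, provider = "morgan_r2",
                                n_bits = 2048) {
  if (is.null(names(smiles))) {
    names(smiles) <- sprintf("cpd_%d", seq_along(smiles))
  }
  provider <- match.arg(provider, c("morgan_r2", "maccs"))
  out <- run_py_worker("rdkit_worker.py", list(
    task = "fingerprint", provider = provider, n_bits = n_bits,
    ids = as.list(names(smiles)), smiles = as.list(unname(smiles))
  ))
  if (!is.null(out$error)) {
    pd_stop(paste("structure error:", out$error), "promdiag_structure_error")
  }
  bits <- unlist(out$bits)[names(smiles)]
  fingerprint_set(bits, provider = provider)
}
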