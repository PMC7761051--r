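#' Interference flag vocabulary
#'
#' Compound-level interference alerts recognized by the curation step:
#' pan-assay interference substructures (PAINS), colloidal aggregators,
#' empirical medicinal-chemistry liabilities, confirmed firefly-luciferase
#' (FLuc) inhibitors, and cytotoxic compounds. Flags are *inputs* to the
#' pipeline (computed upstream by substructure filters); they are never
#' recomputed here.
#' @export
INTERFERENCE_FLAGS <- c("PAINS", "AGGREGATOR", "LIABILITY", "FLUC",
                        "CYTOTOXIC")

#' Assay/compound curation configuration
#'
#' @param max_hit_rate assays (targets) whose hit rate, ACTIVE / tested,
#'   exceeds this fraction are dropped. Default 0.02: screens with hit rates
#'   above 2% are dominated by confirmatory assays and artifacts.
#' @param exclude_flags interference flags whose carriers are removed;
#'   defaults to all of [INTERFERENCE_FLAGS].
#' @return an `AssayFilterConfig` list.
#' @export
assay_filter_config <- function(max_hit_rate = 0.02,
                                exclude_flags = INTERFERENCE_FLAGS) {
  if (!is.numeric(max_hit_rate) || max_hit_rate <= 0 || max_hit_rate > 1) {
    pd_stop("max_hit_rate must be in (0, 1]", "promdiag_config_error")
  }
  bad <- setdiff(exclude_flags, INTERFERENCE_FLAGS)
  if (length(bad)) {
    pd_stop(paste("unknown flags:", paste(bad, collapse = ", ")),
            "promdiag_config_error")
  }
  structure(list(max_hit_rate = max_hit_rate, exclude_flags = exclude_flags),
            class = "AssayFilterConfig")
}

#' Compound library with structures and interference flags
#'
#' @param id compound identifiers (unique).
#' @param smiles optional SMILES strings, parallel to `id`.
#' @param flags optional data.frame with columns `compound_id`, `flag`
#'   (one row per alert; a compound may carry several).
#' @return a `CompoundLibrary` object.
#' @export
compound_library <- function(id, smiles = NULL, flags = NULL) {
  id <- as.character(id)
  if (anyDuplicated(id)) {
    pd_stop("compound identifiers must be unique", "promdiag_config_error")
  }
  if (is.null(flags)) {
    flags <- data.frame(compound_id = character(), flag = character())
  }
  stopifnot(all(c("compound_id", "flag") %in% names(flags)))
  bad <- setdiff(unique(flags$flag), INTERFERENCE_FLAGS)
  if (length(bad)) {
    pd_stop(paste("unknown flags:", paste(bad, collapse = ", ")),
            "promdiag_config_error")
  }
  structure(list(
    records = data.frame(id = id,
                         smiles = if (is.null(smiles)) NA_character_
                                  else as.character(smiles)),
    flags = flags[, c("compound_id", "flag")]
  ), class = "CompoundLibrary")
}

#' Read a compound library from .smi and flags TSV files
#'
#' The `.smi` dialect is one compound per line, `SMILES<whitespace>id`.
#' The flags file is a TSV `compound_id<TAB>flag`, one row per alert.
#'
#' @param smi_path path to the SMILES file (optional, `NULL` to skip).
#' @param flags_path path to the flags TSV (optional).
#' @param ids compound ids to use when no SMILES file is given.
#' @return a `CompoundLibrary`.
#' @export
read_compound_library <- function(smi_path = NULL, flags_path = NULL,
                                  ids = NULL) {
  if (!is.null(smi_path)) {
    lines <- readLines(smi_path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "[[:space:]]+")
    smiles <- vapply(parts, `[`, character(1), 1)
    ids <- vapply(parts, `[`, character(1), 2)
  } else if (is.null(ids)) {
    pd_stop("need smi_path or ids", "promdiag_config_error")
  } else {
    smiles <- NULL
  }
  flags <- NULL
  if (!is.null(flags_path)) {
    flags <- read.delim(flags_path, header = TRUE, colClasses = "character",
                        quote = "")
  }
  compound_library(ids, smiles, flags)
}

#' Remove high-hit-rate assays
#'
#' Drops every target whose hit rate (fraction ACTIVE among tested
#' compounds) exceeds `config$max_hit_rate`, together with all its
#' outcomes; compounds left without any outcome are dropped too. Targets
#' with zero tested compounds have an undefined rate and are dropped.
#'
#' @param x an `ActivityMatrix`.
#' @param config an [assay_filter_config()].
#' @return the filtered `ActivityMatrix`.
#' @export
filter_assays <- function(x, config = assay_filter_config()) {
  tested <- Matrix::colSums(x$m != 0)
  active <- Matrix::colSums(x$m > 0)
  keep <- tested > 0 & (active / pmax(tested, 1)) <= config$max_hit_rate
  m <- x$m[, keep, drop = FALSE]
  m <- m[Matrix::rowSums(m != 0) > 0, , drop = FALSE]
  structure(list(m = m), class = "ActivityMatrix")
}

#' Remove interference-flagged compounds
#'
#' Compounds carrying one or more excluded alerts are removed from the
#' matrix. Per-criterion tallies count every alert, but the final compound
#' count subtracts the *union* of flagged compounds (a compound with
#' multiple alerts is removed once).
#'
#' @param x an `ActivityMatrix`.
#' @param library a [compound_library()] covering every matrix compound.
#' @param config an [assay_filter_config()].
#' @return list with elements `matrix` (curated `ActivityMatrix`) and
#'   `report` (a `CurationReport`: original/final counts and per-flag
#'   tallies).
#' @export
remove_flagged_compounds <- function(x, library,
                                     config = assay_filter_config()) {
  cps <- compounds(x)
  missing <- setdiff(cps, library$records$id)
  if (length(missing)) {
    pd_stop(sprintf("no library record for %d compounds (e.g. '%s')",
                    length(missing), missing[1]),
            "promdiag_lookup_error")
  }
  fl <- library$flags[library$flags$flag %in% config$exclude_flags &
                        library$flags$compound_id %in% cps, ]
  per_flag <- setNames(integer(length(config$exclude_flags)),
                       config$exclude_flags)
  tab <- table(fl$flag)
  per_flag[names(tab)] <- as.integer(tab)
  doomed <- unique(fl$compound_id)
  keep <- setdiff(cps, doomed)
  out <- subset_matrix(x, keep_compounds = keep)
  report <- structure(list(
    original = length(cps),
    removed_per_flag = per_flag,
    removed_total = length(doomed),
    final = length(cps) - length(doomed)
  ), class = "CurationReport")
  list(matrix = out, report = report)
}

#' @export
print.CurationReport <- function(x, ...) {
  cat("Compound curation report\n")
  cat(sprintf("  original pool: %d\n", x$original))
  for (f in names(x$removed_per_flag)) {
    cat(sprintf("  %-11s %d\n", paste0(f, ":"), x$removed_per_flag[[f]]))
  }
  cat(sprintf("  removed (union): %d\n", x$removed_total))
  cat(sprintf("  final selection: %d\n", x$final))
  invisible(x)
}
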