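#' Validate a pipeline configuration file
#'
#' The configuration is a single JSON document (schema version 1). Unknown
#' keys and range violations are rejected with a message listing all
#' failures; missing keys are filled with the standard defaults
#' (PD >= 5, 2% assay hit-rate cap, 80/20 double CV, full model grids,
#' all three dataset conditions).
#'
#' @param path JSON file path.
#' @return a `PipelineConfig` list.
#' @export
validate_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (k in c("inputs", "curation", "grouping", "condition", "protocol",
              "network")) {
    if (!is.null(raw[[k]])) raw[[k]] <- as.list(raw[[k]])
  }
  known <- c("schema_version", "inputs", "curation", "grouping",
             "conditions", "condition", "protocol", "models", "network",
             "seed")
  problems <- character(0)
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    problems <- c(problems, paste("unknown keys:",
                                  paste(unknown, collapse = ", ")))
  }
  inputs <- raw[["inputs"]] %||% list()
  if (is.null(inputs$activity)) {
    problems <- c(problems, "inputs$activity is required")
  }
  for (k in intersect(names(inputs),
                      c("activity", "fingerprints", "flags", "smiles",
                        "ground_truth"))) {
    if (!file.exists(inputs[[k]])) {
      problems <- c(problems, sprintf("input file missing: %s", inputs[[k]]))
    }
  }
  grouping <- raw[["grouping"]] %||% list()
  if (!is.null(grouping$pd_threshold) && grouping$pd_threshold < 2) {
    problems <- c(problems, "pd_threshold must be >= 2")
  }
  cond <- raw[["condition"]] %||% list()
  rf <- cond$removal_fraction %||% 0.5
  fmt <- cond$nn_fraction_mt %||% 0.25
  fst <- cond$nn_fraction_st %||% 0.25
  if (abs(fmt + fst - rf) > 1e-9) {
    problems <- c(problems,
                  "nn_fraction_mt + nn_fraction_st must equal removal_fraction")
  }
  prot <- raw[["protocol"]] %||% list()
  for (k in c("test_fraction", "internal_test_fraction")) {
    v <- prot[[k]]
    if (!is.null(v) && (v <= 0 || v >= 1)) {
      problems <- c(problems, sprintf("%s must lie in (0,1)", k))
    }
  }
  models <- raw[["models"]] %||% c("KNN", "RF", "SVM")
  bad <- setdiff(models, c("KNN", "RF", "SVM"))
  if (length(bad)) {
    problems <- c(problems, paste("unknown models:",
                                  paste(bad, collapse = ", ")))
  }
  conditions <- raw[["conditions"]] %||% c("FULL", "RANDOM_REMOVAL", "NN_REMOVAL")
  bad <- setdiff(conditions, c("FULL", "RANDOM_REMOVAL", "NN_REMOVAL"))
  if (length(bad)) {
    problems <- c(problems, paste("unknown conditions:",
                                  paste(bad, collapse = ", ")))
  }
  if (length(problems)) {
    pd_stop(paste0("invalid configuration:\n  ",
                   paste(problems, collapse = "\n  ")),
            "promdiag_config_error")
  }
  seed <- as.integer(raw[["seed"]] %||% 1L)
  structure(list(
    inputs = inputs,
    curation = assay_filter_config(
      max_hit_rate = raw[["curation"]]$max_hit_rate %||% 0.02,
      exclude_flags = raw[["curation"]]$exclude_flags %||% INTERFERENCE_FLAGS),
    grouping = group_sampling_config(
      pd_threshold = grouping$pd_threshold %||% 5,
      rng_seed = derive_seed(seed, 11L)),
    conditions = conditions,
    condition_params = list(removal_fraction = rf, nn_fraction_mt = fmt,
                            nn_fraction_st = fst),
    protocol = cv_protocol(
      n_external_trials = prot$n_external_trials %||% 10,
      test_fraction = prot$test_fraction %||% 0.2,
      n_internal_trials = prot$n_internal_trials %||% 10,
      internal_test_fraction = prot$internal_test_fraction %||% 0.2),
    models = models,
    network_min_shared = raw[["network"]]$min_shared %||% 50,
    seed = seed
  ), class = "PipelineConfig")
}

#' Run the promiscuity-diagnostics pipeline
#'
#' Executes curate -> sample groups -> NN analysis -> dataset conditions ->
#' diagnostic ML (per model x condition) -> analog statistics -> target
#' network, writing per-stage artifacts to `out_dir` and returning a run
#' report. All randomness derives from `config$seed`.
#'
#' @param config a `PipelineConfig` from [validate_config()], or a path to
#'   a config JSON.
#' @param out_dir output directory.
#' @param stages subset of
#'   `c("curate","groups","nn","reduce","ml","analogs","network")`;
#'   earlier stages a requested stage depends on always run in memory.
#' @return a `promdiag_run` list: `summary` (condition x model means +-
#'   sd), `trials`, `paths`, `n_groups`.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("curate", "groups", "nn", "reduce",
                                    "ml", "analogs", "network")) {
  if (is.character(config)) config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  stage_log <- function(stage, fmt, ...) {
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  fail <- function(stage, e) {
    pd_stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
            "promdiag_stage_error")
  }

  # curate
  mat <- tryCatch({
    m <- read_activity_triplets(config$inputs$activity)
    m <- filter_assays(m, config$curation)
    if (!is.null(config$inputs$flags)) {
      flags <- read.delim(config$inputs$flags, colClasses = "character",
                          quote = "")
      lib <- compound_library(compounds(m), flags = flags)
      cur <- remove_flagged_compounds(m, lib, config$curation)
      if ("curate" %in% stages) {
        paths$curation_report <- file.path(out_dir, "curation_report.json")
        jsonlite::write_json(unclass(cur$report), paths$curation_report,
                             auto_unbox = TRUE, digits = NA)
      }
      cur$matrix
    } else m
  }, error = function(e) fail("curate", e))
  if ("curate" %in% stages) {
    paths$curated <- file.path(out_dir, "curated_activity.tsv")
    write_activity_triplets(mat, paths$curated)
  }
  stage_log("curate", "%d compounds x %d targets retained",
            length(compounds(mat)), length(targets(mat)))

  # groups
  groups <- tryCatch(build_groups(mat, config$grouping),
                     error = function(e) fail("groups", e))
  if (!length(groups)) pd_stop("stage 'groups' produced no MT-/ST-CPD groups",
                               "promdiag_stage_error")
  if ("groups" %in% stages) {
    paths$groups <- file.path(out_dir, "groups.jsonl")
    write_groups(groups, paths$groups)
  }
  stage_log("groups", "%d MT-/ST-CPD groups sampled", length(groups))
  if (!any(c("nn", "reduce", "ml", "analogs", "network") %in% stages)) {
    return(invisible(structure(list(paths = paths,
                                    n_groups = length(groups)),
                               class = "promdiag_run")))
  }

  fps <- if (!is.null(config$inputs$fingerprints)) {
    read_fingerprints(config$inputs$fingerprints)
  } else {
    pd_stop("fingerprints input required beyond the groups stage",
            "promdiag_config_error")
  }
  labels <- group_labels(groups)

  # nn
  if ("nn" %in% stages) {
    prof <- tryCatch(nn_profile(fp_subset(fps, names(labels)), labels),
                     error = function(e) fail("nn", e))
    paths$nn_table <- file.path(out_dir, "nn_profile.tsv")
    export_nn_table(prof, paths$nn_table)
    stage_log("nn", "profiled %d compounds", nrow(prof))
  }

  # reduce: materialize each condition's group list
  cp <- config$condition_params
  cond_groups <- list()
  for (cond in config$conditions) {
    cc <- condition_config(cond, removal_fraction = cp$removal_fraction,
                           nn_fraction_mt = cp$nn_fraction_mt,
                           nn_fraction_st = cp$nn_fraction_st,
                           rng_seed = derive_seed(config$seed, 23L))
    res <- tryCatch(apply_condition(groups, fps, cc),
                    error = function(e) fail("reduce", e))
    cond_groups[[cond]] <- res$groups
    if ("reduce" %in% stages && cond != "FULL") {
      p <- file.path(out_dir, sprintf("groups_%s.jsonl", tolower(cond)))
      write_groups(res$groups, p)
      paths[[paste0("groups_", tolower(cond))]] <- p
      if (!is.null(res$manifest)) {
        mp <- file.path(out_dir, "nn_removal_manifest.tsv")
        write.table(res$manifest, mp, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        paths$nn_removal_manifest <- mp
      }
    }
    stage_log("reduce", "%s: %d groups", cond, length(res$groups))
  }

  trials <- NULL
  if ("ml" %in% stages) {
    all_rows <- list()
    for (cond in config$conditions) {
      for (model in config$models) {
        res <- tryCatch(
          run_double_cv(cond_groups[[cond]], fps, model,
                        protocol = config$protocol,
                        seed = derive_seed(config$seed, 37L)),
          error = function(e) fail("ml", e))
        res$condition <- cond
        all_rows[[paste(cond, model)]] <- res
        if (model %in% c("RF", "SVM")) {
          rp <- file.path(out_dir, sprintf("roc_%s_%s.tsv", tolower(model),
                                           tolower(cond)))
          write.table(attr(res, "roc_first_trial"), rp, sep = "\t",
                      quote = FALSE, row.names = FALSE)
        }
        stage_log("ml", "%s / %s: mean BA %.3f", cond, model,
                  mean(res$BA))
      }
    }
    trials <- do.call(rbind, all_rows)
    class(trials) <- c("promdiag_cv", "data.frame")
    paths$trials <- file.path(out_dir, "trials.tsv")
    write.table(trials, paths$trials, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  # analogs: needs SMILES or ground-truth series labels
  analog_stats <- NULL
  if ("analogs" %in% stages) {
    analog_stats <- tryCatch({
      mt_ids <- vapply(groups, `[[`, character(1), "mt")
      st_ids <- unique(unlist(lapply(groups, function(g) unname(g$st))))
      if (!is.null(config$inputs$smiles)) {
        lib <- read_compound_library(smi_path = config$inputs$smiles)
        smi <- setNames(lib$records$smiles, lib$records$id)
        data.frame(
          class = c("MT", "ST"),
          analog_fraction = c(analog_fraction(smi[mt_ids]),
                              analog_fraction(smi[st_ids])))
      } else if (!is.null(config$inputs$ground_truth)) {
        gt <- read.delim(config$inputs$ground_truth, quote = "")
        cores <- setNames(lapply(gt$series, function(s)
          if (is.na(s)) character(0) else as.character(s)), gt$id)
        data.frame(
          class = c("MT", "ST"),
          analog_fraction = c(analog_fraction(cores = cores[mt_ids]),
                              analog_fraction(cores = cores[st_ids])))
      } else NULL
    }, error = function(e) fail("analogs", e))
    if (!is.null(analog_stats)) {
      paths$analogs <- file.path(out_dir, "analog_fractions.tsv")
      write.table(analog_stats, paths$analogs, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      stage_log("analogs", "MT %.2f / ST %.2f",
                analog_stats$analog_fraction[1],
                analog_stats$analog_fraction[2])
    }
  }

  # network
  if ("network" %in% stages) {
    net <- tryCatch({
      mt_map <- setNames(lapply(groups, `[[`, "targets"),
                         vapply(groups, `[[`, character(1), "mt"))
      build_target_network(mt_map, min_shared = config$network_min_shared)
    }, error = function(e) fail("network", e))
    paths$network <- file.path(out_dir, "target_network.tsv")
    paths$network_graphml <- file.path(out_dir, "target_network.graphml")
    write_target_network(net, paths$network, paths$network_graphml)
    stage_log("network", "%d nodes, %d edges", nrow(net$nodes),
              nrow(net$edges))
  }

  summary_tab <- NULL
  if (!is.null(trials)) {
    summary_tab <- summary.promdiag_cv(trials)
    paths$summary <- file.path(out_dir, "summary.tsv")
    write.table(summary_tab, paths$summary, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(structure(list(summary = summary_tab, trials = trials,
                           analog_stats = analog_stats, paths = paths,
                           n_groups = length(groups)),
                      class = "promdiag_run"))
}

#' @export
print.promdiag_run <- function(x, ...) {
  cat(sprintf("promdiag run: %d groups\n", x$n_groups))
  if (!is.null(x$summary)) {
    print(x$summary[, c(intersect(c("condition", "model"),
                                  names(x$summary)),
                        "BA_mean", "BA_sd", "MCC_mean")])
  }
  invisible(x)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `curate`, `groups`, `nn`, `reduce`, `ml`,
#' `analogs`, `network`, `all`. Shared flags: `--config <json>`,
#' `--seed <int>`, `--out-dir <dir>`. `simulate` writes a synthetic
#' benchmark bundle; the remaining subcommands run the pipeline up to (and
#' including) the named stage. Logs go to stderr, results to files.
#'
#' @param args character vector (defaults to the command line).
#' @return invisibly, the run report or bundle paths.
#' @export
promdiag_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: promdiag <simulate|curate|groups|nn|reduce|ml|",
            "analogs|network|all> [--config F] [--seed N] [--out-dir D]")
    return(invisible(NULL))
  }
  cmd <- args[1]
  opt <- list(seed = 1L, out_dir = "promdiag_out", config = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- args[i]
    val <- if (i + 1 <= length(args)) args[i + 1] else NULL
    switch(key,
      "--config" = { opt$config <- val },
      "--seed" = { opt$seed <- as.integer(val) },
      "--out-dir" = { opt$out_dir <- val },
      pd_stop(paste("unknown flag", key), "promdiag_config_error"))
    i <- i + 2
  }
  if (cmd == "simulate") {
    cfg <- sim_config(rng_seed = opt$seed)
    res <- generate_benchmark(cfg, opt$out_dir)
    message(sprintf("benchmark written to %s", opt$out_dir))
    return(invisible(res))
  }
  stage_seq <- c("curate", "groups", "nn", "reduce", "ml", "analogs",
                 "network")
  stages <- if (cmd == "all") stage_seq else {
    if (!cmd %in% stage_seq) {
      pd_stop(paste("unknown subcommand", cmd), "promdiag_config_error")
    }
    stage_seq[seq_len(match(cmd, stage_seq))]
  }
  if (is.null(opt$config)) {
    pd_stop("--config is required", "promdiag_config_error")
  }
  config <- validate_config(opt$config)
  if (!is.null(opt$seed)) {
    config$seed <- opt$seed
    config$grouping$rng_seed <- derive_seed(opt$seed, 11L)
  }
  run_pipeline(config, opt$out_dir, stages = stages)
}
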