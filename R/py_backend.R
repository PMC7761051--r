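# Bridge to the bundled Python workers.
#
# RF/SVM solver internals are delegated to scikit-learn and SMILES handling
# to RDKit; both run as short-lived subprocesses exchanging JSON (plus flat
# text sidecar files for bulk matrices). Everything scientific -- splits,
# kernels, model selection, metrics -- happens in R.

python_binary <- function() {
  Sys.getenv("PROMDIAG_PYTHON", unset = "python")
}

worker_path <- function(script) {
  p <- system.file("python", script, package = "promdiag")
  if (!nzchar(p)) {
    # source-tree fallback (tests run against installed package normally)
    p <- file.path("inst", "python", script)
  }
  if (!file.exists(p)) {
    pd_stop(sprintf("python worker %s not found", script),
            "promdiag_backend_error")
  }
  p
}

run_py_worker <- function(script, payload, sidecars = list()) {
  dir <- tempfile("promdiag_job_")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  for (nm in names(sidecars)) {
    writeLines(sidecars[[nm]], file.path(dir, nm))
  }
  jsonlite::write_json(payload, file.path(dir, "job.json"),
                       auto_unbox = TRUE, digits = NA)
  res <- suppressWarnings(system2(
    python_binary(), c(worker_path(script), dir),
    stdout = TRUE, stderr = TRUE
  ))
  status <- attr(res, "status") %||% 0L
  out_file <- file.path(dir, "result.json")
  if (status != 0 || !file.exists(out_file)) {
    pd_stop(paste0("python worker failed: ",
                   paste(utils::tail(res, 5), collapse = " | ")),
            "promdiag_backend_error")
  }
  jsonlite::read_json(out_file, simplifyVector = TRUE)
}
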