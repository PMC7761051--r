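#' Analog-relationship configuration
#'
#' Analog detection here is a deliberately simplified single-cut proxy for
#' full fragmentation-based analog-series extraction: every acyclic single
#' bond between heavy atoms is cut once, and the larger fragment counts as
#' a core key when its heavy-atom count is at least
#' `min_core_to_substituent_ratio` times the substituent's. Two compounds
#' are analogs when they share at least one core key. The proxy is
#' validated only on synthetic libraries with known series structure.
#'
#' @param min_core_to_substituent_ratio heavy-atom ratio (default 2).
#' @return an `AnalogConfig`.
#' @export
analog_config <- function(min_core_to_substituent_ratio = 2.0) {
  if (min_core_to_substituent_ratio < 1) {
    pd_stop("ratio must be >= 1", "promdiag_config_error")
  }
  structure(list(min_ratio = min_core_to_substituent_ratio),
            class = "AnalogConfig")
}

#' Single-cut analog core keys for SMILES (RDKit backend)
#'
#' @param smiles named character vector of SMILES.
#' @param config an [analog_config()].
#' @return named list: per compound, a character vector of canonical core
#'   keys (attachment points marked with `*`).
#' @export
fragment_cores <- function(smiles, config = analog_config()) {
  if (is.null(names(smiles))) {
    names(smiles) <- sprintf("cpd_%d", seq_along(smiles))
  }
  out <- run_py_worker("rdkit_worker.py", list(
    task = "fragment", min_ratio = config$min_ratio,
    ids = as.list(names(smiles)), smiles = as.list(unname(smiles))
  ))
  if (!is.null(out$error)) {
    pd_stop(paste("structure error:", out$error), "promdiag_structure_error")
  }
  cores <- out$cores
  # jsonlite may simplify; normalize to character vectors in input order
  lapply(setNames(names(smiles), names(smiles)),
         function(id) as.character(unlist(cores[[id]])))
}

#' Fraction of compounds with at least one structural analog
#'
#' Works either from SMILES (core keys computed via [fragment_cores()]) or
#' from precomputed per-compound key sets (e.g. ground-truth series labels
#' of a synthetic library, where a series id is the shared key).
#'
#' @param smiles named SMILES vector, or `NULL` when `cores` is given.
#' @param cores optional named list of per-compound key vectors.
#' @param config an [analog_config()].
#' @return fraction in \[0, 1\] of compounds sharing >= 1 core key with
#'   another compound.
#' @export
analog_fraction <- function(smiles = NULL, cores = NULL,
                            config = analog_config()) {
  if (is.null(cores)) {
    if (is.null(smiles) || !length(smiles)) {
      pd_stop("empty input", "promdiag_precondition_error")
    }
    cores <- fragment_cores(smiles, config)
  }
  if (!length(cores)) pd_stop("empty input", "promdiag_precondition_error")
  key_df <- data.frame(
    id = rep(names(cores), lengths(cores)),
    key = unlist(cores, use.names = FALSE)
  )
  if (!nrow(key_df)) return(0)
  key_owners <- split(key_df$id, key_df$key)
  shared <- unique(unlist(key_owners[lengths(lapply(key_owners, unique)) >=
                                       2]))
  length(unique(shared)) / length(cores)
}

#' Target network from multi-target compounds
#'
#' Builds the co-occurrence graph of targets: nodes are targets weighted by
#' their MT-CPD counts; an undirected edge connects two targets when they
#' share at least `min_shared` MT-CPDs, weighted by the shared count
#' (default threshold 50).
#'
#' @param mt_target_map named list: MT-CPD id -> character vector of its
#'   active targets (each of length >= 2).
#' @param min_shared minimum shared-MT-CPD count for an edge.
#' @return a `TargetNetwork`: list with `nodes` (data.frame target,
#'   n_mt_cpds), `edges` (data.frame target_a, target_b, shared_count) and
#'   `graph` (an igraph object).
#' @export
build_target_network <- function(mt_target_map, min_shared = 50) {
  if (any(lengths(mt_target_map) < 2)) {
    pd_stop("every MT-CPD must list >= 2 targets",
            "promdiag_precondition_error")
  }
  tgts <- sort(unique(unlist(mt_target_map)))
  inc <- matrix(0L, length(mt_target_map), length(tgts),
                dimnames = list(names(mt_target_map), tgts))
  for (i in seq_along(mt_target_map)) {
    inc[i, mt_target_map[[i]]] <- 1L
  }
  co <- crossprod(inc)                       # shared MT-CPD counts
  nodes <- data.frame(target = tgts, n_mt_cpds = diag(co))
  diag(co) <- 0
  idx <- which(upper.tri(co) & co >= min_shared, arr.ind = TRUE)
  edges <- data.frame(
    target_a = tgts[idx[, 1]], target_b = tgts[idx[, 2]],
    shared_count = co[idx]
  )
  edges <- edges[order(edges$target_a, edges$target_b), , drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) data.frame(from = edges$target_a, to = edges$target_b,
                                weight = edges$shared_count)
    else data.frame(from = character(), to = character(),
                    weight = numeric()),
    directed = FALSE, vertices = data.frame(name = tgts,
                                            size = nodes$n_mt_cpds)
  )
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "TargetNetwork")
}

#' @export
print.TargetNetwork <- function(x, ...) {
  cat(sprintf("TargetNetwork: %d targets, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Write a target network
#'
#' Emits an edge-list TSV (`target_a`, `target_b`, `shared_count`) and,
#' optionally, GraphML with node size = MT-CPD count.
#'
#' @param network a [build_target_network()] result.
#' @param edge_path TSV output path.
#' @param graphml_path optional GraphML output path.
#' @export
write_target_network <- function(network, edge_path, graphml_path = NULL) {
  write.table(network$edges, edge_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(graphml_path)) {
    igraph::write_graph(network$graph, graphml_path, format = "graphml")
  }
  invisible(edge_path)
}
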