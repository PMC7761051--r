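#' Synthetic screening-world configuration
#'
#' The generator emulates the statistical structure the promiscuity
#' analysis relies on: compounds organized in analog series (shared-core
#' fingerprints) of varying tightness, planted MT-CPDs with a fixed
#' promiscuity degree, matched ST-CPDs with explicit negative results
#' (data completeness), ST-CPDs several-fold more abundant than MT-CPDs,
#' high per-compound test frequencies, and the empirical nearest-neighbor
#' asymmetry (MT-CPDs tend to be closer to other MT-CPDs than to ST-CPDs,
#' and more weakly vice versa).
#'
#' Series come in MT/ST role pairs forming *group families*: each member
#' of an MT-role series becomes the multi-target compound of one group,
#' with its own target set of `pd_mt` targets; the paired ST-role series
#' supplies `pd_mt` dedicated single-target compounds per group (one per
#' target slot). With probability `promiscuity_signal` a family is planted
#' *series-coherently* (activity follows the analog structure); otherwise
#' the same activity pattern is planted on structurally random compounds,
#' so at signal 0 chemical structure carries no class information at all.
#'
#' @param n_targets number of assay targets (default 240; with a median
#'   test frequency of ~90 a compound covers ~35% of targets, so a random
#'   PD-1 compound rarely covers a whole group target set, as in real
#'   screening data).
#' @param n_series total number of analog series; consecutive series pair
#'   into MT/ST roles, so `n_series = 50` with `series_size = 8` plants
#'   25 families x 8 = 200 MT-/ST-CPD groups (and 1000 matched ST-CPDs,
#'   a 5:1 ST:MT ratio).
#' @param series_size MT-CPDs per family (scalar or vector to sample
#'   from); the paired ST series holds `series_size * pd_mt` members.
#' @param n_singletons structurally random background compounds
#'   (default 600).
#' @param n_bits fingerprint length (default 2048).
#' @param core_bits_per_series shared bits per series; a length-2 range
#'   (default `c(80, 160)`) from which each series draws its core size, so
#'   series differ in tightness and the nearest-neighbor similarity
#'   distribution is broad rather than degenerate.
#' @param substituent_bits_per_compound private bits per member; a range
#'   (default `c(20, 60)`) drawn per compound.
#' @param promiscuity_signal s in \[0,1\]: probability that a family is
#'   planted series-coherently (default 0.9, the benchmark regime).
#' @param st_coherence probability that a coherent group's ST-CPD comes
#'   from the partner series rather than being structurally random
#'   (default 0.7; makes the ST-side NN tendency weaker than the MT side).
#' @param pd_mt promiscuity degree of planted MT-CPDs (default 5).
#' @param test_frequency_target median assays per compound (default 90).
#' @param background_hit_rate per-outcome activity probability for
#'   background compounds (default 0.002, well under the 2% assay cap).
#' @param label_noise probability of flipping each recorded outcome
#'   (default 0.01; flips can break planted completeness on purpose).
#' @param rng_seed master seed.
#' @return a `SimConfig`.
#' @export
sim_config <- function(n_targets = 240, n_series = 50, series_size = 8,
                       n_singletons = 600, n_bits = 2048,
                       core_bits_per_series = c(80, 160),
                       substituent_bits_per_compound = c(20, 60),
                       promiscuity_signal = 0.9, st_coherence = 0.7,
                       pd_mt = 5, test_frequency_target = 90,
                       background_hit_rate = 0.002, label_noise = 0.01,
                       rng_seed = 1L) {
  if (max(core_bits_per_series) + max(substituent_bits_per_compound) >
        n_bits) {
    pd_stop("core + substituent bits exceed fingerprint length",
            "promdiag_config_error")
  }
  if (promiscuity_signal < 0 || promiscuity_signal > 1 ||
      label_noise < 0 || label_noise > 1) {
    pd_stop("promiscuity_signal and label_noise must lie in [0,1]",
            "promdiag_config_error")
  }
  if (pd_mt > n_targets) {
    pd_stop("pd_mt exceeds the number of targets", "promdiag_config_error")
  }
  structure(as.list(environment()), class = "SimConfig")
}

range_draw <- function(r, n = 1) {
  if (length(r) == 1) rep(as.integer(r), n)
  else sample(seq(min(r), max(r)), n, replace = TRUE)
}

#' Simulate a compound library with analog-series structure
#'
#' Generates fingerprints and ground truth. Each series draws a shared
#' core bit set (size varying between series); members add private
#' substituent bits (count varying between compounds); background
#' singletons draw fully random bit sets of comparable popcount. Planted
#' classes (MT / ST / background) and the per-family coherence draw are
#' assigned here; incoherently planted groups receive fresh structurally
#' random compounds (`x`-prefixed identifiers), so at low signal the
#' planted classes carry no structural information.
#'
#' @param config a [sim_config()].
#' @return list with `fps` (a `FingerprintSet`) and `truth` (data.frame:
#'   `id`; `series`, NA for structurally random compounds; `planted` in
#'   MT/ST/background; `family`; `member`, the group index within the
#'   family; `slot`, the ST target slot).
#' @export
simulate_library <- function(config = sim_config()) {
  with_seed(derive_seed(config$rng_seed, 1L), {
    n_fam <- config$n_series %/% 2L
    sizes <- range_draw(config$series_size, n_fam)
    coherent <- runif(n_fam) < config$promiscuity_signal

    fp_rows <- list()
    truth_rows <- list()
    n_extra <- 0L
    add <- function(id, fp, series, planted, family, member, slot) {
      fp_rows[[id]] <<- fp
      truth_rows[[id]] <<- data.frame(
        id = id, series = series, planted = planted, family = family,
        member = member, slot = slot)
    }
    member_fp <- function(core) {
      sub <- sample(setdiff(seq_len(config$n_bits), core),
                    range_draw(config$substituent_bits_per_compound))
      v <- integer(config$n_bits); v[c(core, sub)] <- 1L
      v
    }
    random_fp <- function() {
      k <- range_draw(config$core_bits_per_series) +
        range_draw(config$substituent_bits_per_compound)
      v <- integer(config$n_bits); v[sample(config$n_bits, k)] <- 1L
      v
    }
    fresh_id <- function() {
      n_extra <<- n_extra + 1L
      sprintf("x%05d", n_extra)
    }

    for (f in seq_len(n_fam)) {
      mt_series <- 2L * f - 1L
      st_series <- 2L * f
      core_mt <- sample(config$n_bits,
                        range_draw(config$core_bits_per_series))
      core_st <- sample(config$n_bits,
                        range_draw(config$core_bits_per_series))
      for (j in seq_len(sizes[f])) {
        if (coherent[f]) {
          add(sprintf("s%03d_m%02d", mt_series, j), member_fp(core_mt),
              mt_series, "MT", f, j, NA_integer_)
        } else {
          # activity planted on a structurally random compound instead;
          # the analog-series member stays in the library as background
          add(sprintf("s%03d_m%02d", mt_series, j), member_fp(core_mt),
              mt_series, "background", NA_integer_, NA_integer_,
              NA_integer_)
          add(fresh_id(), random_fp(), NA_integer_, "MT", f, j,
              NA_integer_)
        }
        for (k in seq_len(config$pd_mt)) {
          if (coherent[f] && runif(1) < config$st_coherence) {
            add(sprintf("s%03d_g%02d_t%d", st_series, j, k),
                member_fp(core_st), st_series, "ST", f, j, k)
          } else if (coherent[f]) {
            add(sprintf("s%03d_g%02d_t%d", st_series, j, k), random_fp(),
                NA_integer_, "ST", f, j, k)
          } else {
            add(fresh_id(), random_fp(), NA_integer_, "ST", f, j, k)
          }
        }
      }
    }
    for (b in seq_len(config$n_singletons)) {
      add(sprintf("bg%04d", b), random_fp(), NA_integer_, "background",
          NA_integer_, NA_integer_, NA_integer_)
    }
    fps <- fingerprint_set(do.call(rbind, fp_rows),
                           provider = "precomputed")
    truth <- do.call(rbind, truth_rows)
    truth <- truth[match(rownames(fps), truth$id), ]
    rownames(truth) <- NULL
    list(fps = fps, truth = truth)
  })
}

#' Simulate the ternary activity matrix for a library
#'
#' Plants one group per (family, member): a target set of `pd_mt` targets
#' drawn independently per group; the group's MT-CPD is active on all of
#' them; each of its ST-CPDs is active on exactly its slot target and
#' explicitly inactive on the rest, so every planted group member carries
#' a recorded outcome for every group target. Remaining tested cells are
#' filled with inactive outcomes on random other targets until each
#' compound reaches its drawn test frequency (normal around the target,
#' 15% CV); background compounds receive random outcomes at
#' `background_hit_rate`. Finally `label_noise` flips each recorded
#' outcome independently, which may break planted completeness --
#' deliberately exercising the verification path.
#'
#' @param library output of [simulate_library()].
#' @param config the same [sim_config()].
#' @return an `ActivityMatrix`.
#' @export
simulate_activity <- function(library, config = sim_config()) {
  truth <- library$truth
  tgt_ids <- sprintf("t%03d", seq_len(config$n_targets))
  with_seed(derive_seed(config$rng_seed, 2L), {
    planted <- truth[!is.na(truth$family), ]
    group_keys <- unique(paste(planted$family, planted$member))
    group_targets <- lapply(group_keys, function(k)
      sample(config$n_targets, config$pd_mt))
    names(group_targets) <- group_keys

    acc <- list()
    emit <- function(c_, t_, o_) {
      acc[[length(acc) + 1L]] <<- list(c = rep(c_, length(t_)), t = t_,
                                       o = o_)
    }
    draw_tf <- function() {
      min(max(config$pd_mt,
              round(rnorm(1, config$test_frequency_target,
                          0.15 * config$test_frequency_target))),
          config$n_targets)
    }

    for (i in seq_len(nrow(truth))) {
      id <- truth$id[i]
      if (truth$planted[i] == "background") {
        tf <- draw_tf()
        tt <- sample(config$n_targets, tf)
        emit(id, tt, as.integer(runif(tf) < config$background_hit_rate))
      } else {
        Tset <- group_targets[[paste(truth$family[i], truth$member[i])]]
        if (truth$planted[i] == "MT") {
          emit(id, Tset, rep(1L, length(Tset)))
        } else {
          o <- integer(length(Tset))
          o[truth$slot[i]] <- 1L
          emit(id, Tset, o)
        }
        extra <- draw_tf() - length(Tset)
        if (extra > 0) {
          pool <- setdiff(seq_len(config$n_targets), Tset)
          tt <- sample(pool, min(extra, length(pool)))
          emit(id, tt, rep(0L, length(tt)))
        }
      }
    }
    cpd <- unlist(lapply(acc, `[[`, "c"))
    tgt <- unlist(lapply(acc, `[[`, "t"))
    out <- unlist(lapply(acc, `[[`, "o"))
    if (config$label_noise > 0) {
      flip <- runif(length(out)) < config$label_noise
      out[flip] <- 1L - out[flip]
    }
    activity_matrix(cpd, tgt_ids[tgt], out)
  })
}

#' Write a complete synthetic benchmark bundle
#'
#' Emits every standard-format input the pipeline consumes: activity
#' triplets TSV, fingerprint TSV, flags TSV, ground-truth TSV and a JSON
#' manifest echoing the configuration (the bundle is self-describing).
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @param flag_fraction fraction of background compounds given a random
#'   interference flag (default 0), for exercising the curation stage.
#' @return invisible list of written paths plus the in-memory objects.
#' @export
generate_benchmark <- function(config = sim_config(), dir,
                               flag_fraction = 0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lib <- simulate_library(config)
  mat <- simulate_activity(lib, config)
  paths <- list(
    matrix = file.path(dir, "activity.tsv"),
    fingerprints = file.path(dir, "fingerprints.tsv"),
    flags = file.path(dir, "flags.tsv"),
    truth = file.path(dir, "ground_truth.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_activity_triplets(mat, paths$matrix)
  write_fingerprints(lib$fps, paths$fingerprints)
  flags <- data.frame(compound_id = character(), flag = character())
  if (flag_fraction > 0) {
    bg <- lib$truth$id[lib$truth$planted == "background"]
    k <- floor(flag_fraction * length(bg))
    flags <- with_seed(derive_seed(config$rng_seed, 3L), {
      data.frame(compound_id = sample(bg, k),
                 flag = sample(INTERFERENCE_FLAGS, k, replace = TRUE))
    })
    flags <- flags[order(flags$compound_id), ]
  }
  write.table(flags, paths$flags, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(lib$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(c(unclass(config),
                         list(flag_fraction = flag_fraction)),
                       paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, list(library = lib, matrix = mat, flags = flags)))
}

#' Small combinatorial SMILES library for analog-detection tests
#'
#' Scaffold + R-group series of real (parseable) structures: each series
#' shares an aromatic/aliphatic scaffold and varies a terminal alkyl
#' chain, which the single-cut analog proxy must recover.
#'
#' @param n_series number of scaffolds to use (max 6).
#' @param series_size members per scaffold.
#' @return named character vector of SMILES; names encode series
#'   membership (`smi<series>_<member>`).
#' @export
simulate_smiles_series <- function(n_series = 2, series_size = 3) {
  scaffolds <- c("c1ccccc1CCN", "c1ccncc1CCO", "C1CCCCC1CCN",
                 "c1ccc2ccccc2c1CC", "c1ccsc1CCO", "c1cnc2ccccc2c1C")
  if (n_series > length(scaffolds)) {
    pd_stop("at most 6 scaffold series available", "promdiag_config_error")
  }
  out <- character(0)
  for (s in seq_len(n_series)) {
    for (m in seq_len(series_size)) {
      out[sprintf("smi%d_%d", s, m)] <-
        paste0(scaffolds[s], strrep("C", m))
    }
  }
  out
}
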