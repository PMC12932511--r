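## End-to-end orchestration: simulate or ingest recordings, condition and
## band-decompose them, optionally source-image scalp data, build networks,
## extract nodal features and densities, then run the statistics and the
## classifier validation. Patients are processed one at a time so cohort
## memory stays bounded.

#' Banded networks and nodal features for one recording
#'
#' Conditioning (optional notch), band decomposition, correlation networks
#' at the given threshold, nodal feature table and per-band EZ/NEZ density
#' reports for a single epoch.
#'
#' @param recording An `ez_recording` (SEEG contacts or source-imaged
#'   regions).
#' @param threshold Binarization threshold (default 0.7).
#' @param band_defs Band definitions; default [band_set()] at the
#'   recording's sampling rate.
#' @param notch_hz Mains frequency to notch out, or `NULL` to skip (the
#'   synthetic generator produces no line noise, so the default skips).
#' @param signed Passed to [binarize()].
#' @return List: `networks` (per band), `features` (nodal feature table),
#'   `densities` (stacked density rows, one per band).
#' @export
network_features <- function(recording, threshold = 0.7, band_defs = NULL,
                             notch_hz = NULL, signed = FALSE) {
  stopifnot(inherits(recording, "ez_recording"))
  if (!is.null(notch_hz))
    recording$data <- notch(recording$data, mains_hz = notch_hz,
                            sampling_rate = recording$sampling_rate)
  banded <- decompose_bands(recording, band_defs)
  networks <- lapply(banded, function(b) binarize(pcc_matrix(b), threshold,
                                                  signed))
  features <- nodal_feature_table(networks)
  densities <- if (!is.null(recording$ez_mask))
    do.call(rbind, lapply(networks, subnetwork_densities)) else NULL
  list(networks = networks, features = features, densities = densities)
}

#' Pipeline configuration
#'
#' @param sim An `ez_sim_config` describing the cohort to simulate, or
#'   `NULL` when reading from a manifest.
#' @param manifest Path to a cohort manifest CSV ([write_cohort()]) when
#'   analysing recorded data.
#' @param states States to analyse; both are needed for the
#'   ictal-vs-interictal density comparison.
#' @param threshold Network threshold (default 0.7).
#' @param esi Run source imaging? Default: automatic, on for scalp data.
#' @param source_model `source_model` for the ESI stage (built on demand if
#'   missing and needed).
#' @param classify Model names to validate (default `"svm"`); `NULL` skips.
#' @param preprocessing Feature preprocessing for the classifiers.
#' @param n_perm Permutations for the significance test; 0 skips.
#' @param seed Master seed, propagated to every stochastic stage.
#' @return An `ez_pipeline_config` list.
#' @export
pipeline_config <- function(sim = simulation_config(), manifest = NULL,
                            states = "interictal", threshold = 0.7,
                            esi = NULL, source_model = NULL,
                            classify = "svm",
                            preprocessing = c("none", "z", "log_z"),
                            n_perm = 0L, seed = 1L) {
  preprocessing <- match.arg(preprocessing)
  if (is.null(sim) && is.null(manifest))
    stopf("either a simulation config or a manifest is required")
  if (!is.null(manifest) && !file.exists(manifest))
    stopf("manifest '%s' does not exist", manifest)
  structure(list(sim = sim, manifest = manifest, states = states,
                 threshold = threshold, esi = esi,
                 source_model = source_model, classify = classify,
                 preprocessing = preprocessing, n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "ez_pipeline_config")
}

#' Run the full localization pipeline
#'
#' Executes simulate/ingest, preprocessing, optional source imaging,
#' network construction, nodal metrics, EZ-vs-NEZ statistics, density
#' analysis (including the ictal-vs-interictal comparison when both states
#' are present) and classifier validation, and assembles everything into a
#' run report. Deterministic for a fixed config and seed.
#'
#' @param config An [pipeline_config()].
#' @return An `ez_run_report`: `features` (pooled nodal feature table),
#'   `stat_tables` (per state), `densities`, `density_comparison` (when two
#'   states), `classifiers`, `permutation`, and `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ez_pipeline_config"))
  t0 <- Sys.time()
  features <- list()
  densities <- list()
  sm <- config$source_model

  for (state in config$states) {
    recs <- pipeline_recordings(config, state)
    for (get_rec in recs) {
      rec <- get_rec()
      use_esi <- config$esi %||% identical(rec$modality, "scalp")
      if (use_esi) {
        if (is.null(sm)) sm <- build_source_model(seed = config$seed)
        rec <- source_image(rec, sm)
      }
      nf <- network_features(rec, threshold = config$threshold)
      nf$features$sample_id <- paste(rec$patient_id, rec$state, sep = ":")
      features[[length(features) + 1L]] <- nf$features
      if (!is.null(nf$densities))
        densities[[length(densities) + 1L]] <- nf$densities
    }
  }
  features <- do.call(rbind, features)
  densities <- if (length(densities)) do.call(rbind, densities) else NULL

  stat_tables <- lapply(stats::setNames(config$states, config$states),
                        function(st) {
    ez_stat_table(features[features$state == st, , drop = FALSE])
  })
  density_cmp <- NULL
  if (!is.null(densities) && all(c("ictal", "interictal") %in% densities$state))
    density_cmp <- density_state_comparison(densities)

  classifiers <- list()
  permutation <- list()
  if (!is.null(config$classify)) {
    for (st in config$states) {
      tab <- balance_classes(features[features$state == st, , drop = FALSE],
                             seed = config$seed)
      for (mod in config$classify) {
        key <- paste(mod, st, sep = ":")
        classifiers[[key]] <- nested_group_cv(
          tab, mod, preprocessing = config$preprocessing, seed = config$seed)
        if (config$n_perm > 0)
          permutation[[key]] <- permutation_test(
            tab, mod, preprocessing = config$preprocessing,
            n_perm = config$n_perm, seed = config$seed)
      }
    }
  }
  structure(
    list(features = features, stat_tables = stat_tables,
         densities = densities, density_comparison = density_cmp,
         classifiers = classifiers, permutation = permutation,
         provenance = list(config = config,
                           elapsed_s = as.numeric(Sys.time() - t0,
                                                  units = "secs"))),
    class = "ez_run_report")
}

# A list of thunks, one per recording, so raw data is materialized one
# patient at a time.
pipeline_recordings <- function(config, state) {
  if (!is.null(config$manifest)) {
    man <- utils::read.csv(config$manifest, stringsAsFactors = FALSE)
    man <- man[man$state == state, , drop = FALSE]
    dir <- dirname(config$manifest)
    return(lapply(man$file, function(f) function() read_edf(file.path(dir, f))))
  }
  sim <- config$sim
  sim$state <- state
  lapply(seq_len(sim$n_patients), function(p) {
    if (sim$modality == "seeg") {
      function() simulate_seeg(sim, patients = p)[[1]]
    } else {
      function() {
        smod <- config$source_model %||% build_source_model(seed = config$seed)
        simulate_scalp(sim, smod, patients = p)[[1]]
      }
    }
  })
}

#' Rank nodes by epileptogenicity score
#'
#' Decision-support output: sorts nodes by the classifier's P(EZ) score
#' (stable sort, so tied scores keep their input order) and returns the
#' top `k`.
#'
#' @param feature_table Nodal feature table with one row per node.
#' @param scores Numeric P(EZ) per row of `feature_table`.
#' @param k Number of candidates to return (default all).
#' @return `feature_table` rows reordered by decreasing score, with a
#'   `score` column, truncated to `k` rows.
#' @export
rank_candidate_nodes <- function(feature_table, scores, k = NULL) {
  if (length(scores) != nrow(feature_table))
    stopf("need one score per node row")
  if (anyNA(scores)) stopf("missing scores")
  ord <- order(-scores)            # radix: stable for ties
  out <- feature_table[ord, , drop = FALSE]
  out$score <- scores[ord]
  if (!is.null(k)) {
    if (k > nrow(out))
      warnf("k = %d exceeds node count %d; returning all", k, nrow(out))
    out <- utils::head(out, k)
  }
  out
}
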