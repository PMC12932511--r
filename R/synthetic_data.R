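## Synthetic cohort generator. Emulates the statistical structure that the
## downstream analysis assumes: in depth recordings the EZ is a small,
## internally loose community weakly coupled to the rest of the network; at
## the scalp the EZ appears as a dominant low-frequency driver whose field
## spread produces a hub-like halo; patients differ by a multiplicative gain.

#' Recording constructor
#'
#' Builds the labelled multichannel container used throughout the pipeline.
#' Mostly called by the simulators and [read_edf()].
#'
#' @param patient_id,modality,state Identifiers ("seeg"/"scalp",
#'   "ictal"/"interictal").
#' @param data Channels x samples numeric matrix.
#' @param sampling_rate Hz.
#' @param channel_labels Optional channel names.
#' @param ez_mask Logical per channel, `TRUE` for EZ contacts. May be omitted
#'   for scalp recordings, where ground truth lives at the source level in
#'   `ez_regions`.
#' @param ez_regions Integer indices of EZ parcels (scalp modality).
#' @param provenance List recording how the object was made (config, seed).
#' @return An `ez_recording`.
#' @export
new_recording <- function(patient_id, modality, state, data, sampling_rate,
                          channel_labels = NULL, ez_mask = NULL,
                          ez_regions = NULL, provenance = list()) {
  check_finite_matrix(data)
  if (is.null(channel_labels))
    channel_labels <- paste0("CH", seq_len(nrow(data)))
  if (!is.null(ez_mask)) {
    ez_mask <- as.logical(ez_mask)
    if (length(ez_mask) != nrow(data))
      stopf("ez_mask length %d != channel count %d", length(ez_mask), nrow(data))
    if (!any(ez_mask) || all(ez_mask))
      stopf("need at least one EZ and one NEZ channel")
  } else if (is.null(ez_regions) && identical(modality, "seeg")) {
    stopf("seeg recordings need an ez_mask")
  }
  structure(
    list(patient_id = patient_id, modality = modality, state = state,
         data = data, sampling_rate = sampling_rate,
         channel_labels = channel_labels, ez_mask = ez_mask,
         ez_regions = ez_regions, provenance = provenance),
    class = "ez_recording"
  )
}

#' @export
print.ez_recording <- function(x, ...) {
  cat(sprintf("<ez_recording> %s | %s %s | %d ch x %d samples @ %g Hz",
              x$patient_id, x$modality, x$state, nrow(x$data),
              ncol(x$data), x$sampling_rate))
  if (!is.null(x$ez_mask)) cat(sprintf(" | %d EZ contacts", sum(x$ez_mask)))
  cat("\n")
  invisible(x)
}

#' Simulation configuration
#'
#' Assembles and validates the knobs of the synthetic cohort generator.
#'
#' The interictal defaults encode the structure the analysis is built to
#' detect: the non-epileptogenic channels share a strong community source
#' (`c_intra_nez`), the EZ channels share a weaker one (`c_intra_ez`), and
#' each community leaks faintly into the other (`c_cross`), so that
#' `c_intra_nez > c_intra_ez > c_cross`. Channel-level coupling jitter
#' (`channel_gain_cv`) spreads pairwise correlations around their expected
#' value, so thresholded edge densities respond smoothly to the couplings
#' rather than saturating. In the ictal state the beta/gamma/HF couplings are
#' multiplied by `ictal_surge`, a shared hypersynchrony source of weight
#' `ictal_hypersync` floods those bands across both communities, and the
#' EZ-internal delta coupling is multiplied by `ictal_delta_boost`
#' (pathological slow-wave resonance). A per-patient log-normal gain with
#' coefficient of variation `patient_gain_cv` (0.4 for SEEG, 0.16 for scalp)
#' scales every coupling, creating the inter-patient heterogeneity that the
#' log + Z feature transform is meant to remove.
#'
#' @param modality "seeg" or "scalp".
#' @param state "interictal" or "ictal".
#' @param n_patients Number of patients in the cohort.
#' @param channels_mean,channels_sd Per-patient SEEG contact count is drawn
#'   from a normal with these moments (defaults 113 and 20), truncated below
#'   at 40. Scalp recordings always use 16 electrodes.
#' @param ez_count_range SEEG EZ contact count range, drawn uniformly
#'   (default 8--30). For scalp, the range of EZ parcel counts (default
#'   5--31).
#' @param sampling_rate Hz; 2000 for SEEG, 500 for scalp.
#' @param epoch_length Seconds per epoch (default 10).
#' @param coupling Named list with `c_intra_nez`, `c_intra_ez`, `c_cross`,
#'   each in \[0, 1\]; either scalars (applied to all bands) or length-7
#'   vectors in [band_set()] order.
#' @param noise_sd Per-band sensor noise standard deviation (signal units).
#' @param patient_gain_cv Coefficient of variation of the per-patient gain.
#' @param channel_gain_cv Coefficient of variation of per-channel coupling
#'   jitter.
#' @param ictal_surge Multiplier on beta/gamma/HF couplings in the ictal
#'   state (default 2).
#' @param ictal_hypersync Weight of the shared ictal hypersynchrony source in
#'   beta/gamma/HF (default 1.5); this is what lets cross-community
#'   correlations break the network threshold during seizures.
#' @param ictal_delta_boost Multiplier on the EZ-internal delta coupling in
#'   the ictal state (default 1.8).
#' @param ez_amp_ratio Scalp only: amplitude of the EZ slow-wave driver
#'   relative to background sources (must exceed 1; default 5).
#' @param seed Integer seed; every patient derives a sub-seed from it.
#' @return A validated `ez_sim_config` list.
#' @export
simulation_config <- function(modality = c("seeg", "scalp"),
                              state = c("interictal", "ictal"),
                              n_patients = 20,
                              channels_mean = 113, channels_sd = 20,
                              ez_count_range = NULL,
                              sampling_rate = NULL,
                              epoch_length = 10,
                              coupling = list(c_intra_nez = 0.9,
                                              c_intra_ez = 0.55,
                                              c_cross = 0.2),
                              noise_sd = 0.45,
                              patient_gain_cv = NULL,
                              channel_gain_cv = 0.3,
                              ictal_surge = 2.0,
                              ictal_hypersync = 1.5,
                              ictal_delta_boost = 1.8,
                              ez_amp_ratio = 5,
                              seed = 1L) {
  modality <- match.arg(modality)
  state <- match.arg(state)
  sampling_rate <- sampling_rate %||% if (modality == "seeg") 2000 else 500
  patient_gain_cv <- patient_gain_cv %||% if (modality == "seeg") 0.4 else 0.16
  ez_count_range <- ez_count_range %||%
    if (modality == "seeg") c(8L, 30L) else c(5L, 31L)

  cpl <- unlist(coupling[c("c_intra_nez", "c_intra_ez", "c_cross")])
  if (anyNA(cpl) || any(cpl < 0) || any(cpl > 1))
    stopf("coupling values must all lie in [0, 1]")
  if (noise_sd <= 0) stopf("noise_sd must be positive")
  if (epoch_length <= 0 || (epoch_length * sampling_rate) %% 1 != 0)
    stopf("epoch_length x sampling_rate must be a positive integer")
  if (ez_count_range[1] < 1) stopf("ez_count_range must start at >= 1")
  if (modality == "scalp" && ez_amp_ratio <= 1)
    stopf("ez_amp_ratio must exceed 1 (the EZ driver must dominate)")

  structure(
    list(modality = modality, state = state, n_patients = n_patients,
         channels_mean = channels_mean, channels_sd = channels_sd,
         ez_count_range = as.integer(ez_count_range),
         sampling_rate = sampling_rate, epoch_length = epoch_length,
         coupling = coupling, noise_sd = noise_sd,
         patient_gain_cv = patient_gain_cv,
         channel_gain_cv = channel_gain_cv,
         ictal_surge = ictal_surge, ictal_hypersync = ictal_hypersync,
         ictal_delta_boost = ictal_delta_boost,
         ez_amp_ratio = ez_amp_ratio, seed = as.integer(seed)),
    class = "ez_sim_config"
  )
}

# Per-band coupling table for a config, with the ictal adjustments applied.
# Returns data.frame(name, a = intra-NEZ, e = intra-EZ, x = cross leak,
# w = shared hypersync weight).
coupling_table <- function(config, bands) {
  expand1 <- function(v) if (length(v) == 1L) rep(v, nrow(bands)) else
    v[match(bands$name, c("full", "delta", "theta", "alpha", "beta", "gamma", "hf"))]
  a <- expand1(config$coupling$c_intra_nez)
  e <- expand1(config$coupling$c_intra_ez)
  x <- expand1(config$coupling$c_cross)
  w <- rep(0, nrow(bands))
  if (config$state == "ictal") {
    hi <- bands$name %in% c("beta", "gamma", "hf")
    a[hi] <- a[hi] * config$ictal_surge
    e[hi] <- e[hi] * config$ictal_surge
    x[hi] <- x[hi] * config$ictal_surge
    w[hi] <- config$ictal_hypersync
    e[bands$name == "delta"] <- e[bands$name == "delta"] * config$ictal_delta_boost
  }
  data.frame(name = bands$name, a = a, e = e, x = x, w = w,
             stringsAsFactors = FALSE)
}

# Unit-variance band-limited latent: white noise filtered into [low, high].
band_latent <- function(n, low, high, fs) {
  x <- suppressWarnings(bandpass(rnorm(n), low, high, sampling_rate = fs))
  x / stats::sd(x)
}

# Narrow-band latents are generated per band; the component bands used for
# synthesis exclude the full band (which is their superposition).
synthesis_bands <- function(fs) {
  b <- band_set(fs)
  b[b$name != "full", , drop = FALSE]
}

#' Simulate an SEEG cohort
#'
#' Generates depth-electrode recordings in which each channel is a weighted
#' mixture of band-limited community sources plus independent band-limited
#' noise (see [simulation_config()] for the generative model). EZ contacts
#' couple to their own weak community source; NEZ contacts to a strong one;
#' each community leaks into the other with the smallest weight. The result,
#' after network construction, is an EZ that is internally loose and weakly
#' attached -- the isolated-node phenotype -- with ictal surges confined to
#' the configured bands.
#'
#' @param config An `ez_sim_config` with `modality = "seeg"`.
#' @param patients Optional integer vector selecting a subset of patients to
#'   generate (results are identical to generating the full cohort and
#'   subsetting, which keeps per-patient memory bounded in long cohorts).
#' @return A list of `ez_recording` objects.
#' @export
simulate_seeg <- function(config, patients = NULL) {
  stopifnot(inherits(config, "ez_sim_config"))
  if (config$modality != "seeg") stopf("config modality must be 'seeg'")
  patients <- patients %||% seq_len(config$n_patients)
  lapply(patients, function(p) simulate_seeg_patient(config, p))
}

simulate_seeg_patient <- function(config, p) {
  fs <- config$sampling_rate
  n_s <- round(config$epoch_length * fs)
  bands <- synthesis_bands(fs)
  cpl <- coupling_table(config, bands)
  with_seed(config$seed * 1000L + p, {
    n_ch <- max(40L, round(rnorm(1, config$channels_mean, config$channels_sd)))
    ez_max <- min(config$ez_count_range[2], n_ch - 10L)
    n_ez <- sample(config$ez_count_range[1]:ez_max, 1)
    ez_mask <- rep(FALSE, n_ch)
    ez_mask[sample.int(n_ch, n_ez)] <- TRUE
    g <- rlnorm_cv(1, config$patient_gain_cv)
    u <- rlnorm_cv(n_ch, config$channel_gain_cv)

    white <- matrix(rnorm(n_ch * n_s), n_ch, n_s)
    noise_bands <- multiband_filter(white, bands, fs)
    data <- matrix(0, n_ch, n_s)
    for (b in seq_len(nrow(bands))) {
      lo <- bands$low_hz[b]; hi <- bands$high_hz[b]
      s_nez <- band_latent(n_s, lo, hi, fs)
      s_ez <- band_latent(n_s, lo, hi, fs)
      s_hyp <- if (cpl$w[b] > 0) band_latent(n_s, lo, hi, fs) else NULL
      w_own <- ifelse(ez_mask, cpl$e[b], cpl$a[b]) * g * u
      w_leak <- cpl$x[b] * g * u
      own <- ifelse(ez_mask, 1, 0)
      data <- data +
        tcrossprod(w_own * own + w_leak * (1 - own), s_ez) +
        tcrossprod(w_own * (1 - own) + w_leak * own, s_nez)
      if (!is.null(s_hyp))
        data <- data + tcrossprod(cpl$w[b] * g * u, s_hyp)
      noise <- noise_bands[[b]] / apply(noise_bands[[b]], 1, stats::sd)
      data <- data + config$noise_sd * noise
    }
    new_recording(
      patient_id = sprintf("P%02d", p), modality = "seeg",
      state = config$state, data = data, sampling_rate = fs,
      ez_mask = ez_mask,
      provenance = list(config = config, seed = config$seed * 1000L + p,
                        patient_gain = g)
    )
  })
}

#' Simulate a scalp EEG cohort
#'
#' Places a shared high-amplitude delta/theta driver at the EZ source
#' locations, independent low-amplitude broadband background at NEZ sources,
#' projects everything to the 16 electrodes through the forward model of
#' `source_model`, and adds sensor noise. Ground-truth EZ labels are recorded
#' at the parcel level (`ez_regions`); after source reconstruction the EZ
#' parcels appear as a correlated high-amplitude halo -- the hub phenotype.
#'
#' @param config An `ez_sim_config` with `modality = "scalp"`.
#' @param source_model A `source_model` from [build_source_model()] with 16
#'   electrodes.
#' @param patients Optional subset of patient indices.
#' @return A list of `ez_recording` objects (16 channels each).
#' @export
simulate_scalp <- function(config, source_model, patients = NULL) {
  stopifnot(inherits(config, "ez_sim_config"),
            inherits(source_model, "source_model"))
  if (config$modality != "scalp") stopf("config modality must be 'scalp'")
  if (nrow(source_model$electrodes) != 16L)
    stopf("scalp simulation expects a 16-electrode montage")
  patients <- patients %||% seq_len(config$n_patients)
  lapply(patients, function(p) simulate_scalp_patient(config, source_model, p))
}

simulate_scalp_patient <- function(config, sm, p) {
  fs <- config$sampling_rate
  n_s <- round(config$epoch_length * fs)
  n_src <- nrow(sm$sources)
  regions <- sort(unique(sm$parcellation))
  with_seed(config$seed * 1000L + p, {
    n_ez <- sample(config$ez_count_range[1]:
                   min(config$ez_count_range[2], length(regions) - 1L), 1)
    ez_regions <- sort(sample(regions, n_ez))
    ez_src <- sm$parcellation %in% ez_regions
    g <- rlnorm_cv(1, config$patient_gain_cv)

    # shared pathological slow-wave driver (delta + theta)
    drv <- band_latent(n_s, 0.5, 4, fs) + 0.7 * band_latent(n_s, 4, 8, fs)
    drv <- drv / stats::sd(drv)
    bg_hi <- min(45, 0.45 * fs)

    # moments: radial orientation at each source location
    J <- matrix(0, 3 * n_src, n_s)
    amp_ez <- config$ez_amp_ratio
    for (l in seq_len(n_src)) {
      ori <- sm$sources[l, ] / sqrt(sum(sm$sources[l, ]^2))
      tc <- if (ez_src[l]) {
        g * amp_ez * (0.9 * drv + 0.45 * band_latent(n_s, 0.5, 8, fs))
      } else {
        g * (band_latent(n_s, 0.5, bg_hi, fs) +
               0.3 * band_latent(n_s, 0.5, 4, fs))
      }
      J[(3 * l - 2):(3 * l), ] <- outer(ori, tc)
    }
    phi <- sm$K %*% J
    phi <- phi + config$noise_sd * matrix(rnorm(length(phi)), nrow(phi))
    new_recording(
      patient_id = sprintf("P%02d", p), modality = "scalp",
      state = config$state, data = phi, sampling_rate = fs,
      channel_labels = rownames(sm$electrodes),
      ez_regions = ez_regions,
      provenance = list(config = config, seed = config$seed * 1000L + p,
                        patient_gain = g)
    )
  })
}
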