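## Filtering and epoching. All filters are zero-phase (forward-backward),
## built from Butterworth designs factored into second-order sections:
## high-order narrow-band transfer functions (e.g. 0.5-4 Hz at 2 kHz) are
## numerically unstable in expanded polynomial form, while biquad cascades
## remain well-conditioned.

# Design an order-`order` Butterworth band-pass as a list of biquads.
# Mirrors signal::butter (bilinear transform with frequency pre-warping) but
# keeps the factored zero-pole form.
butter_bandpass_sos <- function(order, low_hz, high_hz, sampling_rate) {
  W <- c(low_hz, high_hz) / (sampling_rate / 2)
  Tn <- 2
  Ww <- (2 / Tn) * tan(pi * W / 2)
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  s <- signal::sftrans(signal::Zpg(zero = complex(0), pole = proto, gain = 1),
                       W = Ww, stop = FALSE)
  z <- signal::bilinear(s, T = Tn)
  pole <- z$pole[order(Mod(z$pole))]
  used <- rep(FALSE, length(pole))
  sections <- list()
  for (i in seq_along(pole)) {
    if (used[i]) next
    used[i] <- TRUE
    j <- which(!used & Mod(pole - Conj(pole[i])) < 1e-8)[1]
    pair <- if (is.na(j)) {
      # real pole: pair real poles together
      j2 <- which(!used & abs(Im(pole)) < 1e-8)[1]
      if (is.na(j2)) c(pole[i], 0) else { used[j2] <- TRUE; c(pole[i], pole[j2]) }
    } else {
      used[j] <- TRUE
      c(pole[i], pole[j])
    }
    sections[[length(sections) + 1L]] <- pair
  }
  g <- Re(z$gain)^(1 / length(sections))
  # each section carries one zero at z = 1 and one at z = -1 (band-pass)
  lapply(sections, function(p) {
    list(b = g * c(1, 0, -1),
         a = Re(c(1, -(p[1] + p[2]), p[1] * p[2])))
  })
}

sos_filtfilt_vec <- function(sos, x) {
  for (s in sos) x <- signal::filtfilt(s$b, s$a, x)
  x
}

apply_rows <- function(data, fun) {
  out <- data
  for (i in seq_len(nrow(data))) out[i, ] <- fun(data[i, ])
  out
}

# Evaluate a polynomial in z^-1 with coefficients `coef` at e^{i w}.
poly_eval_z <- function(coef, w) {
  h <- 0 + 0i
  for (k in seq_along(coef)) h <- h + coef[k] * exp(-1i * w * (k - 1))
  h
}

# |H(e^{i w})|^2 of a biquad cascade on the given digital frequencies.
sos_magnitude_sq <- function(sos, w) {
  e1 <- exp(-1i * w)
  e2 <- exp(-2i * w)
  h <- rep(1 + 0i, length(w))
  for (s in sos) {
    h <- h * (s$b[1] + s$b[2] * e1 + s$b[3] * e2) /
      (s$a[1] + s$a[2] * e1 + s$a[3] * e2)
  }
  Mod(h)^2
}

# Zero-phase filtering in the frequency domain: multiply the spectrum of
# each channel by the real gain |H|^2 evaluated on the FFT grid. This is
# the steady-state response of forward-backward filtering, computed with
# circular boundary conditions (no startup transients).
fft_zero_phase <- function(data, gain) {
  n <- ncol(data)
  sp <- stats::mvfft(t(data))
  sp <- sp * gain
  out <- Re(stats::mvfft(sp, inverse = TRUE)) / n
  t(out)
}

fft_gain_grid <- function(n, sampling_rate) {
  f <- seq_len(n) - 1L
  f <- ifelse(f > n / 2, f - n, f)          # signed bin frequencies
  2 * pi * abs(f) / n                       # digital rad/sample, symmetric
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass forward and backward (zero net
#' phase, squared magnitude response) to each channel. Band edges above
#' `0.45 * sampling_rate` are clipped with a warning.
#'
#' @param data Numeric matrix, channels x samples (a plain vector is treated
#'   as one channel).
#' @param low_hz,high_hz Band edges in Hz, `0 < low_hz < high_hz`.
#' @param order Filter order of the underlying Butterworth design (default 4).
#' @param sampling_rate Sampling rate in Hz.
#' @param method `"fft"` (default) applies the squared-magnitude response on
#'   the FFT grid -- the exact steady-state forward-backward response, with
#'   circular boundary conditions and no startup transient; `"sos"` runs the
#'   biquad cascade forward and backward in the time domain.
#' @return Filtered data with the same shape as the input.
#' @export
bandpass <- function(data, low_hz, high_hz, order = 4, sampling_rate,
                     method = c("fft", "sos")) {
  method <- match.arg(method)
  vec <- is.null(dim(data))
  if (vec) data <- matrix(data, nrow = 1)
  check_finite_matrix(data)
  if (low_hz <= 0 || low_hz >= high_hz)
    stopf("need 0 < low_hz < high_hz (got %g, %g)", low_hz, high_hz)
  cap <- 0.45 * sampling_rate
  if (high_hz > cap) {
    warnf("high_hz %g clipped to 0.45 x sampling_rate = %g", high_hz, cap)
    high_hz <- cap
  }
  if (low_hz >= high_hz)
    stopf("band collapsed after Nyquist capping (low %g >= high %g)", low_hz, high_hz)
  sos <- butter_bandpass_sos(order, low_hz, high_hz, sampling_rate)
  out <- if (method == "fft") {
    w <- fft_gain_grid(ncol(data), sampling_rate)
    fft_zero_phase(data, sos_magnitude_sq(sos, w))
  } else {
    apply_rows(data, function(x) sos_filtfilt_vec(sos, x))
  }
  if (vec) drop(out) else out
}

#' Zero-phase mains notch filter
#'
#' Removes power-line interference with a band-stop of width `stopband_hz`
#' centred at `mains_hz` and, optionally, at every harmonic below the Nyquist
#' frequency.
#'
#' @inheritParams bandpass
#' @param mains_hz Mains frequency in Hz (50 for most of the world, 60 in the
#'   Americas).
#' @param stopband_hz Total stop-band width in Hz (default 2, i.e. +/- 1 Hz).
#' @param harmonics Notch every integer harmonic below Nyquist?
#' @return Filtered data with the same shape as the input.
#' @export
notch <- function(data, mains_hz = 50, stopband_hz = 2, harmonics = TRUE,
                  sampling_rate, method = c("fft", "sos")) {
  method <- match.arg(method)
  vec <- is.null(dim(data))
  if (vec) data <- matrix(data, nrow = 1)
  check_finite_matrix(data)
  if (stopband_hz <= 0) stopf("stopband_hz must be positive")
  nyq <- sampling_rate / 2
  if (mains_hz >= nyq) stopf("mains_hz must lie below the Nyquist frequency")
  freqs <- notch_frequencies(mains_hz, nyq, harmonics, stopband_hz)
  filters <- lapply(freqs, function(f0) {
    w <- c(f0 - stopband_hz / 2, f0 + stopband_hz / 2) / nyq
    signal::butter(2, w, type = "stop")
  })
  if (method == "fft") {
    w <- fft_gain_grid(ncol(data), sampling_rate)
    gain <- rep(1, length(w))
    for (flt in filters) {
      h <- poly_eval_z(flt$b, w) / poly_eval_z(flt$a, w)
      gain <- gain * Mod(h)^2
    }
    data <- fft_zero_phase(data, gain)
  } else {
    for (flt in filters) {
      data <- apply_rows(data, function(x) signal::filtfilt(flt, x))
    }
  }
  if (vec) drop(data) else data
}

# Harmonic centre frequencies whose stop band fits under Nyquist.
notch_frequencies <- function(mains_hz, nyquist_hz, harmonics, stopband_hz = 2) {
  ks <- if (harmonics) seq_len(floor(nyquist_hz / mains_hz)) else 1L
  f <- ks * mains_hz
  f[f + stopband_hz / 2 < nyquist_hz]
}

#' Extract a fixed-length epoch from a recording
#'
#' @param recording An `ez_recording` (see [simulate_seeg()]).
#' @param start_s Window start in seconds from the beginning of the recording.
#' @param duration_s Window length in seconds (default 10).
#' @return An `ez_recording` containing `duration_s * sampling_rate` samples,
#'   with all metadata preserved.
#' @export
extract_epoch <- function(recording, start_s, duration_s = 10) {
  stopifnot(inherits(recording, "ez_recording"))
  fs <- recording$sampling_rate
  n <- ncol(recording$data)
  i0 <- round(start_s * fs) + 1L
  len <- round(duration_s * fs)
  if (start_s < 0 || i0 + len - 1L > n)
    stopf("window [%g, %g] s outside recording of %g s", start_s,
          start_s + duration_s, n / fs)
  recording$data <- recording$data[, i0:(i0 + len - 1L), drop = FALSE]
  recording
}

# One forward FFT, one inverse per band: returns a named list of filtered
# channels x samples matrices, one per row of band_defs.
multiband_filter <- function(data, band_defs, sampling_rate, order = 4) {
  n <- ncol(data)
  w <- fft_gain_grid(n, sampling_rate)
  sp <- stats::mvfft(t(data))
  out <- lapply(seq_len(nrow(band_defs)), function(i) {
    hi <- min(band_defs$high_hz[i], 0.45 * sampling_rate)
    sos <- butter_bandpass_sos(order, band_defs$low_hz[i], hi, sampling_rate)
    gain <- sos_magnitude_sq(sos, w)
    t(Re(stats::mvfft(sp * gain, inverse = TRUE)) / n)
  })
  names(out) <- band_defs$name
  out
}

#' Decompose an epoch into frequency-band components
#'
#' Band-pass filters a recording into each band of `band_defs` (by default
#' the seven analysis bands from [band_set()]), returning one banded epoch per
#' band.
#'
#' @param recording An `ez_recording`.
#' @param band_defs A data.frame as returned by [band_set()].
#' @return A named list of `ez_banded` objects, one per band, each carrying
#'   the band definition plus the filtered channels x samples matrix.
#' @export
decompose_bands <- function(recording, band_defs = NULL) {
  stopifnot(inherits(recording, "ez_recording"))
  fs <- recording$sampling_rate
  if (is.null(band_defs)) band_defs <- band_set(fs)
  if (nrow(band_defs) == 0L) stopf("empty band set")
  filtered_bands <- multiband_filter(recording$data, band_defs, fs)
  out <- lapply(seq_len(nrow(band_defs)), function(i) {
    bd <- band_defs[i, ]
    filtered <- filtered_bands[[i]]
    structure(
      list(band = bd$name, low_hz = bd$low_hz, high_hz = bd$high_hz,
           data = filtered, sampling_rate = fs,
           patient_id = recording$patient_id,
           modality = recording$modality, state = recording$state,
           channel_labels = recording$channel_labels,
           ez_mask = recording$ez_mask),
      class = "ez_banded"
    )
  })
  names(out) <- band_defs$name
  out
}
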