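#' Analysis frequency bands
#'
#' Returns the set of frequency bands used throughout the pipeline. The seven
#' default bands are the full band plus the six classical EEG rhythms: delta
#' (0.5--4 Hz), theta (4--8 Hz), alpha (8--13 Hz), beta (13--30 Hz), gamma
#' (30--80 Hz) and the high-frequency band (HF, above 80 Hz). The HF upper
#' edge is capped at `min(300, 0.45 * sampling_rate)` so the band stays inside
#' the digitally representable range; the full band spans 0.5 Hz to the same
#' upper edge.
#'
#' @param sampling_rate Sampling rate in Hz. Needed to place the HF upper
#'   edge; bands whose lower edge reaches the cap are dropped with a warning.
#' @param bands Character vector selecting a subset of
#'   `c("full","delta","theta","alpha","beta","gamma","hf")`.
#' @return A data.frame with columns `name`, `low_hz`, `high_hz`.
#' @examples
#' band_set(500)
#' band_set(2000, bands = c("delta", "gamma"))
#' @export
band_set <- function(sampling_rate,
                     bands = c("full", "delta", "theta", "alpha",
                               "beta", "gamma", "hf")) {
  if (sampling_rate <= 0) stopf("sampling_rate must be positive")
  upper <- min(300, 0.45 * sampling_rate)
  defs <- data.frame(
    name    = c("full", "delta", "theta", "alpha", "beta", "gamma", "hf"),
    low_hz  = c(0.5, 0.5, 4, 8, 13, 30, 80),
    high_hz = c(upper, 4, 8, 13, 30, 80, upper),
    stringsAsFactors = FALSE
  )
  bands <- match.arg(bands, defs$name, several.ok = TRUE)
  defs <- defs[match(bands, defs$name), , drop = FALSE]
  keep <- defs$low_hz < defs$high_hz
  if (!all(keep)) {
    warnf("dropping band(s) %s: empty after capping at %.1f Hz",
          paste(defs$name[!keep], collapse = ", "), upper)
    defs <- defs[keep, , drop = FALSE]
  }
  if (nrow(defs) == 0L) stopf("no valid bands at sampling rate %g", sampling_rate)
  rownames(defs) <- NULL
  defs
}
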