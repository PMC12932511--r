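## Minimal EDF (European Data Format) I/O. Covers the classic EDF layout:
## fixed 256-byte header, one 256-byte header block per signal, then data
## records of 2-byte little-endian integers with per-signal linear scaling.
## EDF+ annotation channels are not interpreted. Sufficient for exchanging
## simulated cohorts and for round-tripping uniform-rate clinical epochs.

pad <- function(x, width) formatC(as.character(x), width = width, flag = "-")

#' Write a recording to an EDF file
#'
#' All channels must share one sampling rate (the layout used by this
#' pipeline). Data are scaled per channel to the full 16-bit integer range,
#' so round-tripped values carry a relative quantisation error of about 1e-4.
#' A JSON sidecar with the EZ mask and provenance is written next to the EDF
#' when `sidecar = TRUE`.
#'
#' @param recording An `ez_recording`.
#' @param path Output file path (".edf").
#' @param sidecar Also write `<path>.json` with patient id, state, EZ mask
#'   and the generator seed?
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, sidecar = TRUE) {
  stopifnot(inherits(recording, "ez_recording"))
  data <- recording$data
  fs <- recording$sampling_rate
  ns <- nrow(data)
  n_samp <- ncol(data)
  rec_dur <- 1
  spr <- round(fs * rec_dur)            # samples per record per signal
  n_rec <- floor(n_samp / spr)
  if (n_rec < 1) { rec_dur <- n_samp / fs; spr <- n_samp; n_rec <- 1L }
  n_used <- n_rec * spr

  # Physical min/max live in 8-byte ASCII header fields. Use bounds that
  # are exactly representable in 8 characters AND contain the data range,
  # and reuse those same rounded values for the integer scaling, so writer
  # and reader agree exactly.
  lo <- apply(data[, seq_len(n_used), drop = FALSE], 1, min)
  hi <- apply(data[, seq_len(n_used), drop = FALSE], 1, max)
  span <- pmax(hi - lo, 1e-6 * pmax(abs(hi), 1), 1e-12)
  bound8 <- function(v, target, up) {
    pad_frac <- 1e-3
    repeat {
      cand <- v + (if (up) pad_frac else -pad_frac) * span
      s <- vapply(cand, function(x) {
        for (d in 7:1) {
          str <- formatC(x, format = "g", digits = d)
          if (nchar(str) <= 8) return(str)
        }
        "0"
      }, "")
      num <- as.numeric(s)
      ok <- if (up) num >= target else num <= target
      if (all(ok)) return(list(num = num, str = s))
      pad_frac <- pad_frac * 4
    }
  }
  bmin <- bound8(lo, lo, up = FALSE)
  bmax <- bound8(hi, hi, up = TRUE)
  pmin_ <- bmin$num
  pmax_ <- bmax$num

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8),
    pad(sprintf("patient %s", recording$patient_id), 80),
    pad(sprintf("eznet %s %s", recording$modality, recording$state), 80),
    pad("01.01.26", 8), pad("00.00.00", 8),
    pad(256 * (ns + 1), 8),
    pad("", 44),
    pad(n_rec, 8),
    pad(format(rec_dur), 8),
    pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  lab <- recording$channel_labels %||% paste0("CH", seq_len(ns))
  fields <- c(
    pad(substr(lab, 1, 16), 16),
    pad(rep("", ns), 80),
    pad(rep("uV", ns), 8),
    pad(bmin$str, 8),
    pad(bmax$str, 8),
    pad(rep(-32768, ns), 8),
    pad(rep(32767, ns), 8),
    pad(rep("", ns), 80),
    pad(rep(spr, ns), 8),
    pad(rep("", ns), 32)
  )
  writeChar(paste(fields, collapse = ""), con, eos = NULL)

  scale <- (pmax_ - pmin_) / 65535
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    block <- round((data[, idx, drop = FALSE] - pmin_) / scale) - 32768
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  if (sidecar) {
    meta <- list(patient_id = recording$patient_id,
                 modality = recording$modality, state = recording$state,
                 sampling_rate = fs,
                 ez_mask = recording$ez_mask,
                 ez_regions = recording$ez_regions,
                 seed = recording$provenance$seed)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         null = "null")
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Requires all signals to share one sampling rate. If a JSON sidecar written
#' by [write_edf()] is present it supplies the EZ mask and state metadata.
#'
#' @param path Path to an EDF file.
#' @return An `ez_recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)                                   # version
  patient <- trimws(rd(80))
  rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  labels <- fld(16); fld(80); fld(8)
  pmin_ <- as.numeric(fld(8)); pmax_ <- as.numeric(fld(8))
  dmin_ <- as.numeric(fld(8)); dmax_ <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8)); fld(32)
  if (length(unique(spr)) != 1L)
    stopf("read_edf supports a single sampling rate; file mixes %s",
          paste(unique(spr), collapse = "/"))
  fs <- spr[1] / rec_dur
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = ns * spr[1], size = 2,
                   endian = "little")
    block <- matrix(raw, nrow = spr[1], ncol = ns)
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    data[, idx] <- t(block)
  }
  scale <- (pmax_ - pmin_) / (dmax_ - dmin_)
  data <- (data - dmin_) * scale + pmin_

  meta <- NULL
  sc <- paste0(path, ".json")
  if (file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  new_recording(
    patient_id = meta$patient_id %||% patient,
    modality = meta$modality %||% "seeg",
    state = meta$state %||% "interictal",
    data = data, sampling_rate = fs, channel_labels = labels,
    ez_mask = if (!is.null(meta$ez_mask)) as.logical(meta$ez_mask) else NULL,
    ez_regions = meta$ez_regions,
    provenance = list(source = path, seed = meta$seed)
  )
}

#' Write a cohort manifest
#'
#' Writes one EDF (+ JSON sidecar) per recording and a CSV manifest listing
#' file, patient, modality and state, for batch processing.
#'
#' @param recordings List of `ez_recording` objects.
#' @param dir Output directory (created if needed).
#' @return Path to the manifest CSV, invisibly.
#' @export
write_cohort <- function(recordings, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(recordings, function(rec) {
    fn <- sprintf("%s_%s_%s.edf", rec$patient_id, rec$modality, rec$state)
    write_edf(rec, file.path(dir, fn))
    data.frame(file = fn, patient_id = rec$patient_id,
               modality = rec$modality, state = rec$state,
               n_channels = nrow(rec$data),
               sampling_rate = rec$sampling_rate,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mf <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mf, row.names = FALSE)
  invisible(mf)
}
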