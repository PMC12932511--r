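## Functional networks: Pearson correlation matrices and their binarization
## by an absolute threshold.

#' Pearson correlation connectivity matrix
#'
#' Pairwise Pearson correlation between channels over the epoch. Channels
#' with zero variance yield r = 0 off-diagonal (with a warning) so node
#' indexing stays aligned with clinical labels instead of failing.
#'
#' @param x An `ez_banded` epoch, `ez_recording`, or a channels x samples
#'   matrix.
#' @return An `ez_connectivity` object: `values` (symmetric, unit diagonal),
#'   `labels`, plus `band`/`state` metadata when available.
#' @export
pcc_matrix <- function(x) {
  meta <- list(band = NULL, state = NULL, ez_mask = NULL, labels = NULL,
               patient_id = NULL, modality = NULL)
  if (inherits(x, c("ez_banded", "ez_recording"))) {
    meta$band <- x$band %||% "full"
    meta$state <- x$state
    meta$ez_mask <- x$ez_mask
    meta$labels <- x$channel_labels
    meta$patient_id <- x$patient_id
    meta$modality <- x$modality
    x <- x$data
  }
  check_finite_matrix(x)
  if (nrow(x) < 2L) stopf("need at least 2 channels")
  if (ncol(x) < 2L) stopf("need at least 2 samples")
  sds <- apply(x, 1, stats::sd)
  degenerate <- sds < .Machine$double.eps
  r <- suppressWarnings(stats::cor(t(x)))
  if (any(degenerate)) {
    warnf("%d zero-variance channel(s); correlations set to 0",
          sum(degenerate))
    r[degenerate, ] <- 0
    r[, degenerate] <- 0
  }
  diag(r) <- 1
  r <- (r + t(r)) / 2
  labels <- meta$labels %||% rownames(x) %||% paste0("CH", seq_len(nrow(x)))
  dimnames(r) <- list(labels, labels)
  structure(list(values = r, labels = labels, band = meta$band,
                 state = meta$state, ez_mask = meta$ez_mask,
                 patient_id = meta$patient_id, modality = meta$modality),
            class = "ez_connectivity")
}

#' Binarize a connectivity matrix
#'
#' Builds the unweighted, undirected network: an edge is present where the
#' absolute correlation reaches the threshold, `|r_ij| >= T`, with the
#' diagonal forced to zero. `signed = TRUE` restricts edges to positive
#' correlations (`r_ij >= T`), for sensitivity analyses of the thresholding
#' convention.
#'
#' @param conn An `ez_connectivity` from [pcc_matrix()].
#' @param threshold T in (0, 1); default 0.7.
#' @param signed Keep only positive correlations?
#' @return An `ez_network` with binary `adjacency`, `threshold`, `labels`,
#'   and metadata.
#' @export
binarize <- function(conn, threshold = 0.7, signed = FALSE) {
  stopifnot(inherits(conn, "ez_connectivity"))
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be in (0, 1)")
  r <- if (signed) conn$values else abs(conn$values)
  a <- (r >= threshold) * 1L
  diag(a) <- 0L
  a <- pmax(a, t(a))  # exact symmetry
  structure(list(adjacency = a, threshold = threshold, signed = signed,
                 labels = conn$labels, band = conn$band, state = conn$state,
                 ez_mask = conn$ez_mask, patient_id = conn$patient_id,
                 modality = conn$modality),
            class = "ez_network")
}

#' @export
print.ez_network <- function(x, ...) {
  cat(sprintf("<ez_network> %d nodes, %d edges, T = %g%s%s\n",
              nrow(x$adjacency), sum(x$adjacency) / 2, x$threshold,
              if (!is.null(x$band)) paste0(", band ", x$band) else "",
              if (!is.null(x$state)) paste0(", ", x$state) else ""))
  invisible(x)
}

#' Networks across a threshold sweep
#'
#' Re-binarizes one connectivity matrix at several thresholds (default the
#' sensitivity set 0.6, 0.7, 0.8), so downstream metrics can be checked for
#' robustness to the threshold choice. Edge sets are nested: raising T can
#' only remove edges.
#'
#' @inheritParams binarize
#' @param thresholds Numeric vector of thresholds in (0, 1).
#' @return Named list of `ez_network`, one per threshold.
#' @export
threshold_sweep <- function(conn, thresholds = c(0.6, 0.7, 0.8),
                            signed = FALSE) {
  if (length(thresholds) == 0L) stopf("empty threshold list")
  out <- lapply(thresholds, function(tt) binarize(conn, tt, signed))
  names(out) <- paste0("T", thresholds)
  out
}
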