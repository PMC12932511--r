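## Paired EZ-vs-NEZ hypothesis testing. Comparisons are paired within each
## sample (patient x epoch): nodal metrics are aggregated over the EZ nodes
## and over the NEZ nodes of the same network, and the per-sample pairs are
## tested with the Wilcoxon signed-rank test. The exact null distribution is
## computed by dynamic programming over the realized (possibly tied) ranks,
## which reproduces full sign enumeration at any n without 2^n cost;
## stats::wilcox.test offers the exact path only for untied data, which
## thresholded network metrics routinely violate.

#' Aggregate nodal features into paired EZ/NEZ samples
#'
#' For every sample and every feature column, collapses the EZ-node values
#' and the NEZ-node values with `aggregator` (mean by default, the
#' convention used throughout the package; median available).
#'
#' @param feature_table A nodal feature table ([nodal_feature_table()] rows,
#'   possibly concatenated over patients/epochs) with `ez_label` and
#'   `patient_id` columns; an optional `sample_id` column distinguishes
#'   multiple epochs of one patient.
#' @param aggregator `"mean"` or `"median"`.
#' @return data.frame: `sample_id`, `feature`, `ez_value`, `nez_value`.
#' @export
aggregate_pairs <- function(feature_table, aggregator = c("mean", "median")) {
  aggregator <- match.arg(aggregator)
  agg <- if (aggregator == "mean") mean else stats::median
  ft <- feature_table
  if (is.null(ft$sample_id)) ft$sample_id <- ft$patient_id
  feat_cols <- feature_columns(ft)
  out <- list()
  for (sid in unique(ft$sample_id)) {
    sub <- ft[ft$sample_id == sid, , drop = FALSE]
    ez <- sub$ez_label == "EZ"
    if (!any(ez) || all(ez))
      stopf("sample %s lacks an EZ or NEZ node", sid)
    for (fc in feat_cols) {
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sid, feature = fc,
        ez_value = agg(sub[[fc]][ez]),
        nez_value = agg(sub[[fc]][!ez]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Feature columns of a nodal feature table: everything after the metadata.
feature_columns <- function(ft) {
  meta <- c("patient_id", "node", "state", "modality", "ez_label",
            "sample_id", "group", "label")
  setdiff(names(ft), meta)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired observations. Zero differences are
#' dropped (Wilcoxon's convention). With at most `exact_max` informative
#' pairs the p-value is exact -- the null distribution of the rank sum is
#' built over the realized ranks, ties included, equivalent to enumerating
#' all sign assignments -- otherwise a normal approximation with continuity
#' and tie correction is used. Fewer than five informative pairs yields an
#' undefined (NA) p-value with `flag = "too_few_pairs"`.
#'
#' @param x,y Paired numeric vectors (or `y = NULL` to test differences
#'   supplied directly in `x`).
#' @param exact_max Largest n for which the exact distribution is used
#'   (default 25).
#' @return List: `statistic` (rank sum of positive differences), `p`, `n`
#'   informative pairs, `direction` (sign of the median difference),
#'   `method`, `flag` (`NA` when clean).
#' @export
paired_wilcoxon <- function(x, y = NULL, exact_max = 25L) {
  d <- if (is.null(y)) x else x - y
  if (anyNA(d)) stopf("missing values in paired differences")
  d <- d[d != 0]
  n <- length(d)
  direction <- sign(stats::median(d))
  if (n == 0L)
    return(list(statistic = NA_real_, p = NA_real_, n = 0L, direction = 0,
                method = "none", flag = "all_zero"))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n < 5L)
    return(list(statistic = W, p = NA_real_, n = n, direction = direction,
                method = "none", flag = "too_few_pairs"))
  if (n <= exact_max) {
    p <- signed_rank_exact_p(r, W)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = W, p = p, n = n, direction = direction, method = method,
       flag = NA_character_)
}

# Exact two-sided p for the signed-rank sum over realized ranks `r`
# (average ranks allowed: doubling makes them integers). The distribution
# of W+ under random signs is built by convolution; identical to averaging
# over all 2^n sign assignments.
signed_rank_exact_p <- function(r, W) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  counts <- c(1, rep(0, total))        # counts[w + 1] over doubled sums
  for (ri in r2) {
    shifted <- c(rep(0, ri), counts[seq_len(total + 1 - ri)])
    counts <- counts + shifted
  }
  probs <- counts / 2^length(r2)
  w2 <- as.integer(round(2 * W))
  p_le <- sum(probs[seq_len(w2 + 1)])
  p_ge <- sum(probs[(w2 + 1):(total + 1)])
  min(1, 2 * min(p_le, p_ge))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control (a validating wrapper around
#' `p.adjust(method = "BH")`): values are returned in input order, clipped
#' at 1, and are non-decreasing in raw-p rank order.
#'
#' @param p Numeric vector of p-values in \[0, 1\]; NAs pass through.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' EZ-vs-NEZ statistical table over all band x metric features
#'
#' Runs the paired Wilcoxon test on every feature of a paired sample table
#' and applies BH correction across the family (all band x metric tests of
#' one modality x state table).
#'
#' @param paired A paired table from [aggregate_pairs()], or a nodal feature
#'   table (aggregated internally with the mean).
#' @param alternative direction is always reported; the test is two-sided.
#' @return data.frame: `feature`, `band`, `metric`, `n`, `statistic`, `p`,
#'   `p_adj`, `direction` (+1 when EZ > NEZ), `flag`.
#' @export
ez_stat_table <- function(paired) {
  if (!all(c("feature", "ez_value", "nez_value") %in% names(paired)))
    paired <- aggregate_pairs(paired)
  feats <- unique(paired$feature)
  rows <- lapply(feats, function(fc) {
    sub <- paired[paired$feature == fc, ]
    w <- paired_wilcoxon(sub$ez_value, sub$nez_value)
    parts <- strsplit(fc, "_", fixed = TRUE)[[1]]
    data.frame(feature = fc,
               band = parts[1],
               metric = paste(parts[-1], collapse = "_"),
               n = w$n, statistic = w$statistic, p = w$p,
               direction = w$direction, flag = w$flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out[, c("feature", "band", "metric", "n", "statistic", "p", "p_adj",
          "direction", "flag")]
}

#' Ictal-vs-interictal comparison of sub-network densities
#'
#' Pairs the density reports of matched samples across the two states and
#' tests each density type within each band with the paired Wilcoxon test,
#' BH-corrected within the densities x bands family.
#'
#' @param densities data.frame of stacked [subnetwork_densities()] rows for
#'   both states (columns `patient_id`, `band`, `state`, `d_ez`, `d_nez`,
#'   `d_cross`).
#' @param states Character vector of length 2: the state treated as "test"
#'   (first) and "reference" (second); direction +1 means test > reference.
#' @return data.frame: `band`, `density`, `n`, `p`, `p_adj`, `direction`,
#'   `flag`.
#' @export
density_state_comparison <- function(densities,
                                     states = c("ictal", "interictal")) {
  stopifnot(all(states %in% densities$state))
  rows <- list()
  for (band in unique(densities$band)) {
    for (dtype in c("d_ez", "d_nez", "d_cross")) {
      a <- densities[densities$band == band & densities$state == states[1], ]
      b <- densities[densities$band == band & densities$state == states[2], ]
      common <- intersect(a$patient_id, b$patient_id)
      if (length(common) < length(union(a$patient_id, b$patient_id)))
        stopf("unmatched samples between states in band %s", band)
      av <- a[[dtype]][match(common, a$patient_id)]
      bv <- b[[dtype]][match(common, b$patient_id)]
      keep <- !is.na(av) & !is.na(bv)
      w <- paired_wilcoxon(av[keep], bv[keep])
      rows[[length(rows) + 1L]] <- data.frame(
        band = band, density = dtype, n = w$n, statistic = w$statistic,
        p = w$p, direction = w$direction, flag = w$flag,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out[, c("band", "density", "n", "statistic", "p", "p_adj", "direction",
          "flag")]
}
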