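## EEG forward and inverse problem on a concentric multi-shell spherical
## head model. The forward solution expands the dipole potential in
## spherical harmonics and solves the per-degree radial boundary-value
## problem numerically for the layered conductor, which keeps the code
## correct for any number of shells and any conductivity profile without
## relying on a memorized closed form. The inverse stage is the classical
## regularized minimum norm with an average-reference projector, followed by
## sLORETA standardization by the resolution-based variance.

#' Three-shell spherical head model
#'
#' @param radii Outer radius of each shell, innermost first (normalized
#'   units; defaults brain 0.87, skull 0.92, scalp 1.0).
#' @param conductivities Conductivity of each shell in S/m (defaults 0.33,
#'   0.0042, 0.33 -- a 1:1/80:1 skull profile).
#' @return A `head_model` list.
#' @export
head_model <- function(radii = c(0.87, 0.92, 1.0),
                       conductivities = c(0.33, 0.0042, 0.33)) {
  if (length(radii) != length(conductivities))
    stopf("radii and conductivities must have equal length")
  if (is.unsorted(radii, strictly = TRUE))
    stopf("radii must be strictly increasing, innermost first")
  if (any(conductivities <= 0)) stopf("conductivities must be positive")
  structure(list(radii = radii, conductivities = conductivities),
            class = "head_model")
}

#' Idealized 16-channel 10--20 montage on the unit sphere
#'
#' Spherical-cap positions for the 16 electrodes most common in clinical
#' practice (Fp1/2, F3/4, F7/8, C3/4, T3/4, P3/4, T5/6, O1/2), projected on
#' a sphere of radius `scalp_radius`. The layout is the standard spherical
#' idealization of the 10--20 system, not digitized anatomy.
#'
#' @param scalp_radius Radius of the outer shell the electrodes sit on.
#' @return A 16 x 3 matrix of electrode coordinates with row names.
#' @export
montage_1020_16 <- function(scalp_radius = 1.0) {
  ring <- function(labels, az_deg, incl_deg) {
    az <- az_deg * pi / 180
    incl <- incl_deg * pi / 180
    m <- cbind(sin(incl) * cos(az), sin(incl) * sin(az),
               rep(cos(incl), length(az)))
    rownames(m) <- labels
    m
  }
  outer_ring <- ring(
    c("Fp1", "Fp2", "F7", "F8", "T3", "T4", "T5", "T6", "O1", "O2"),
    c(108, 72, 144, 36, 180, 0, 216, 324, 252, 288), 85)
  mid_ring <- ring(c("F3", "F4", "C3", "C4", "P3", "P4"),
                   c(120, 60, 180, 0, 240, 300), 45)
  scalp_radius * rbind(outer_ring, mid_ring)
}

# Quasi-uniform directions via the Fibonacci spiral.
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Build a source model: grid, parcellation and lead field
#'
#' Lays out `n_regions` parcel centroids quasi-uniformly in the source shell,
#' places `sources_per_region` dipole locations around each centroid (so
#' every parcel is non-empty by construction), and computes the lead field.
#'
#' @param montage Electrode matrix (rows = electrodes) on the outer shell;
#'   default [montage_1020_16()].
#' @param n_regions Number of parcels (default 148, 74 per hemisphere in the
#'   default symmetric layout).
#' @param sources_per_region Dipole locations per parcel (default 2).
#' @param model A [head_model()].
#' @param source_depth Fraction of the innermost radius at which centroids
#'   are placed (default 0.7).
#' @param seed Seed for the small centroid jitter.
#' @return A `source_model` with elements `electrodes`, `sources` (N_V x 3),
#'   `parcellation` (region index per source), `K` (N_E x 3 N_V lead field,
#'   average-referenced) and `head_model`.
#' @export
build_source_model <- function(montage = montage_1020_16(),
                               n_regions = 148, sources_per_region = 2,
                               model = head_model(), source_depth = 0.7,
                               seed = 1L) {
  r_in <- model$radii[1]
  centroids <- fibonacci_directions(n_regions) * source_depth * r_in
  with_seed(seed, {
    src <- do.call(rbind, lapply(seq_len(n_regions), function(r) {
      jitter <- matrix(rnorm(3 * sources_per_region, sd = 0.03 * r_in),
                       sources_per_region, 3)
      pts <- centroids[rep(r, sources_per_region), , drop = FALSE] + jitter
      # keep strictly inside the innermost shell
      len <- sqrt(rowSums(pts^2))
      too_far <- len > 0.85 * r_in
      pts[too_far, ] <- pts[too_far, , drop = FALSE] *
        (0.85 * r_in / len[too_far])
      pts
    }))
    parc <- rep(seq_len(n_regions), each = sources_per_region)
    build_lead_field(montage, src, model, parcellation = parc)
  })
}

#' Compute the lead field for arbitrary source positions
#'
#' Solves the EEG forward problem for unit dipoles in the x, y and z
#' directions at every source location, on the layered spherical conductor.
#' Rows are average-referenced, so each column of `K` sums to zero across
#' electrodes and the solution is invariant to the recording reference.
#'
#' @param montage Electrode coordinate matrix (rows on the outer shell).
#' @param sources N_V x 3 matrix of dipole locations strictly inside the
#'   innermost shell.
#' @param model A [head_model()].
#' @param parcellation Optional integer vector mapping each source to a
#'   region.
#' @param n_max Truncation degree of the spherical-harmonic series.
#' @return A `source_model` (see [build_source_model()]).
#' @export
build_lead_field <- function(montage, sources, model = head_model(),
                             parcellation = NULL, n_max = 60L) {
  montage <- as.matrix(montage)
  sources <- as.matrix(sources)
  R <- model$radii[length(model$radii)]
  er <- sqrt(rowSums(montage^2))
  if (any(abs(er - R) > 1e-6 * R))
    stopf("electrodes must lie on the outer shell (radius %g)", R)
  if (anyDuplicated(round(montage, 10)))
    stopf("coincident electrode positions")
  b <- sqrt(rowSums(sources^2))
  if (any(b >= model$radii[1]))
    stopf("sources must lie strictly inside the innermost shell")
  if (!is.null(parcellation)) {
    if (length(parcellation) != nrow(sources))
      stopf("parcellation length must equal the source count")
    if (any(tabulate(parcellation) == 0))
      stopf("every region must contain at least one source")
  }
  G <- shell_transfer(model, n_max)
  n_e <- nrow(montage)
  n_v <- nrow(sources)
  K <- matrix(0, n_e, 3 * n_v)
  for (l in seq_len(n_v)) {
    K[, (3 * l - 2):(3 * l)] <-
      dipole_potentials(montage, sources[l, ], model, G, n_max)
  }
  K <- K - matrix(colMeans(K), n_e, 3 * n_v, byrow = TRUE)  # average reference
  dimnames(K) <- list(rownames(montage), NULL)
  structure(list(electrodes = montage, sources = sources,
                 parcellation = parcellation, K = K, head_model = model,
                 n_max = n_max),
            class = "source_model")
}

#' @export
print.source_model <- function(x, ...) {
  cat(sprintf("<source_model> %d electrodes, %d sources, %s shells",
              nrow(x$electrodes), nrow(x$sources),
              length(x$head_model$radii)))
  if (!is.null(x$parcellation))
    cat(sprintf(", %d regions", length(unique(x$parcellation))))
  cat("\n")
  invisible(x)
}

# Per-degree transfer coefficients of the layered sphere: G[n] maps the
# source's outgoing multipole coefficient (the r^-(n+1) term of the
# infinite-medium expansion in the innermost layer) to the potential
# coefficient on the outer surface. Obtained by solving, for each degree,
# the linear system imposed by potential and current continuity at the
# interfaces and zero current at the scalp.
shell_transfer <- function(model, n_max) {
  r <- model$radii
  s <- model$conductivities
  L <- length(r)
  R <- r[L]
  vapply(seq_len(n_max), function(n) {
    if (L == 1L) {
      # single shell: V = r^-(n+1) + A r^n, dV/dr(R) = 0
      A <- (n + 1) * R^(-(2 * n + 1)) / n
      return(A * R^n + R^(-(n + 1)))
    }
    # unknowns: A_1, then (A_j, B_j) for j = 2..L
    n_unk <- 1L + 2L * (L - 1L)
    M <- matrix(0, n_unk, n_unk)
    rhs <- numeric(n_unk)
    idxA <- function(j) if (j == 1L) 1L else 2L * (j - 1L)
    idxB <- function(j) 2L * (j - 1L) + 1L       # only j >= 2
    row <- 0L
    for (j in seq_len(L - 1L)) {
      rj <- r[j]
      # potential continuity at r_j
      row <- row + 1L
      M[row, idxA(j)] <- rj^n
      if (j > 1L) M[row, idxB(j)] <- rj^(-(n + 1))
      M[row, idxA(j + 1L)] <- -rj^n
      M[row, idxB(j + 1L)] <- -rj^(-(n + 1))
      if (j == 1L) rhs[row] <- -rj^(-(n + 1))
      # radial current continuity at r_j
      row <- row + 1L
      M[row, idxA(j)] <- s[j] * n * rj^(n - 1)
      if (j > 1L) M[row, idxB(j)] <- -s[j] * (n + 1) * rj^(-(n + 2))
      M[row, idxA(j + 1L)] <- -s[j + 1L] * n * rj^(n - 1)
      M[row, idxB(j + 1L)] <- s[j + 1L] * (n + 1) * rj^(-(n + 2))
      if (j == 1L) rhs[row] <- s[j] * (n + 1) * rj^(-(n + 2))
    }
    # zero current at the outer surface
    row <- row + 1L
    M[row, idxA(L)] <- n * R^(n - 1)
    M[row, idxB(L)] <- -(n + 1) * R^(-(n + 2))
    sol <- solve(M, rhs)
    sol[idxA(L)] * R^n + sol[idxB(L)] * R^(-(n + 1))
  }, numeric(1))
}

# Legendre P_n(x) and associated P_n^1(x) (positive convention,
# P_n^1 = sqrt(1-x^2) dP_n/dx) for n = 1..n_max, vectorized over x.
# Returns list(P = n_max x length(x), P1 = same shape).
legendre_tables <- function(x, n_max) {
  m <- length(x)
  P <- matrix(0, n_max, m)
  P1 <- matrix(0, n_max, m)
  sx <- sqrt(pmax(0, 1 - x^2))
  p_prev <- rep(1, m)   # P_0
  p_cur <- x            # P_1
  P[1, ] <- p_cur
  q_prev <- rep(0, m)   # P_0^1
  q_cur <- sx           # P_1^1
  P1[1, ] <- q_cur
  if (n_max >= 2) {
    for (n in 1:(n_max - 1)) {
      p_next <- ((2 * n + 1) * x * p_cur - n * p_prev) / (n + 1)
      q_next <- ((2 * n + 1) * x * q_cur - (n + 1) * q_prev) / n
      P[n + 1, ] <- p_next
      P1[n + 1, ] <- q_next
      p_prev <- p_cur; p_cur <- p_next
      q_prev <- q_cur; q_cur <- q_next
    }
  }
  list(P = P, P1 = P1)
}

# Rotation matrix mapping unit vector v to the +z axis.
rotation_to_z <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) return(diag(3))
  v <- v / nv
  z <- c(0, 0, 1)
  c_ <- sum(v * z)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  axis <- c(v[2] * z[3] - v[3] * z[2],
            v[3] * z[1] - v[1] * z[3],
            v[1] * z[2] - v[2] * z[1])
  s_ <- sqrt(sum(axis^2))
  axis <- axis / s_
  Kx <- matrix(c(0, -axis[3], axis[2],
                 axis[3], 0, -axis[1],
                 -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + s_ * Kx + (1 - c_) * (Kx %*% Kx)
}

# Electrode potentials (N_E x 3) for unit x/y/z dipoles at one source.
dipole_potentials <- function(electrodes, src, model, G, n_max) {
  sigma1 <- model$conductivities[1]
  R <- model$radii[length(model$radii)]
  b <- sqrt(sum(src^2))
  rot <- rotation_to_z(src)
  e_rot <- electrodes %*% t(rot)
  ct <- pmin(1, pmax(-1, e_rot[, 3] / R))
  phi_az <- atan2(e_rot[, 2], e_rot[, 1])
  lt <- legendre_tables(ct, n_max)
  nn <- seq_len(n_max)
  b_pow <- if (b == 0) c(1, rep(0, n_max - 1)) else b^(nn - 1)
  wn <- G * b_pow / (4 * pi * sigma1)
  alpha <- as.numeric(crossprod(lt$P, wn * nn))   # radial weight per electrode
  beta <- as.numeric(crossprod(lt$P1, wn))        # tangential weight
  # potential of moment m (original frame): m . t(rot) %*% c(beta cos, beta sin, alpha)
  loc <- rbind(beta * cos(phi_az), beta * sin(phi_az), alpha)
  t(t(rot) %*% loc)   # N_E x 3? -> (3 x N_E) transposed
}

#' Regularized minimum-norm inverse solution
#'
#' Estimates dipole moments from scalp potentials by minimizing
#' `||phi - K J - c 1||^2 + alpha ||J||^2` over `J` and the reference
#' constant `c`. The constant is absorbed by the average-reference centering
#' projector `H`, giving `J = K' (K K' + alpha H)^+ H phi`.
#'
#' @param phi Electrode potentials: vector or N_E x samples matrix.
#' @param K Lead field (N_E x 3 N_V), or a `source_model`.
#' @param alpha Regularization parameter (>= 0), or `"auto"` for
#'   `1e-6 * mean(diag(K K'))`.
#' @return A `3 N_V x samples` matrix of moment estimates with attribute
#'   `"alpha"`.
#' @export
minimum_norm_solve <- function(phi, K, alpha = "auto") {
  if (inherits(K, "source_model")) K <- K$K
  if (is.null(dim(phi))) phi <- matrix(phi, ncol = 1)
  if (nrow(phi) != nrow(K))
    stopf("phi has %d rows but K has %d electrodes", nrow(phi), nrow(K))
  n_e <- nrow(K)
  KKt <- tcrossprod(K)
  if (identical(alpha, "auto")) alpha <- 1e-6 * mean(diag(KKt))
  if (alpha < 0) stopf("alpha must be non-negative")
  H <- diag(n_e) - matrix(1 / n_e, n_e, n_e)
  Minv <- MASS::ginv(KKt + alpha * H)
  J <- crossprod(K, Minv %*% (H %*% phi))
  attr(J, "alpha") <- alpha
  J
}

#' sLORETA standardization of a minimum-norm estimate
#'
#' Scales the minimum-norm moments by the inverse of their resolution-based
#' variance: for source `l` with 3 x 3 variance block `S_ll` taken from
#' `K'(K K' + alpha H)^+ K`, the standardized power is
#' `J_l' S_ll^{-1} J_l`. For noiseless single-dipole data this statistic
#' peaks exactly at the true source (the zero-localization-error property).
#'
#' @param J_hat Moment estimates from [minimum_norm_solve()].
#' @param K Lead field or `source_model` used for the estimate.
#' @param alpha The regularization used in the solve (or `"auto"`, matching
#'   [minimum_norm_solve()]'s default).
#' @return N_V x samples matrix of non-negative standardized power.
#' @export
sloreta_standardize <- function(J_hat, K, alpha = "auto") {
  if (inherits(K, "source_model")) K <- K$K
  n_v <- ncol(K) / 3
  if (nrow(J_hat) != ncol(K))
    stopf("J_hat rows (%d) must equal 3 x N_V (%d)", nrow(J_hat), ncol(K))
  n_e <- nrow(K)
  KKt <- tcrossprod(K)
  if (identical(alpha, "auto")) alpha <- 1e-6 * mean(diag(KKt))
  H <- diag(n_e) - matrix(1 / n_e, n_e, n_e)
  Minv <- MASS::ginv(KKt + alpha * H)
  power <- matrix(0, n_v, ncol(J_hat))
  for (l in seq_len(n_v)) {
    idx <- (3 * l - 2):(3 * l)
    Kl <- K[, idx, drop = FALSE]
    Sll <- crossprod(Kl, Minv %*% Kl)
    Sinv <- tryCatch(solve(Sll), error = function(e) {
      warnf("singular variance block at source %d; using pseudoinverse", l)
      MASS::ginv(Sll)
    })
    Jl <- J_hat[idx, , drop = FALSE]
    power[l, ] <- colSums(Jl * (Sinv %*% Jl))
  }
  pmax(power, 0)
}

#' Collapse source activity to region time series
#'
#' Averages the per-source magnitude time course within each parcel. Pass
#' the square root of the sLORETA standardized power (the default used by
#' [run_pipeline()]) or any non-negative source-level matrix.
#'
#' @param source_activity N_V x samples matrix.
#' @param parcellation Integer region index per source.
#' @param ez_regions Optional EZ region indices, recorded in the result.
#' @return A `region_ts` list with `data` (regions x samples), `regions`,
#'   and `ez_region_mask`.
#' @export
parcellate <- function(source_activity, parcellation, ez_regions = NULL) {
  if (nrow(source_activity) != length(parcellation))
    stopf("parcellation length must match the source count")
  regions <- sort(unique(parcellation))
  if (any(tabulate(match(parcellation, regions)) == 0))
    stopf("empty region in parcellation")
  data <- do.call(rbind, lapply(regions, function(r) {
    colMeans(source_activity[parcellation == r, , drop = FALSE])
  }))
  rownames(data) <- paste0("R", regions)
  structure(list(data = data, regions = regions,
                 ez_region_mask = if (!is.null(ez_regions))
                   regions %in% ez_regions else NULL),
            class = "region_ts")
}

#' Full source-imaging stage for one scalp recording
#'
#' Runs minimum-norm + sLORETA on a scalp epoch and parcellates the
#' square-root standardized power into region time series, carrying the EZ
#' region labels along.
#'
#' @param recording A scalp `ez_recording`.
#' @param source_model A `source_model`.
#' @param alpha Regularization (see [minimum_norm_solve()]).
#' @return An `ez_recording` whose channels are the parcellation regions.
#' @export
source_image <- function(recording, source_model, alpha = "auto") {
  stopifnot(inherits(recording, "ez_recording"),
            inherits(source_model, "source_model"))
  J <- minimum_norm_solve(recording$data, source_model, alpha)
  pw <- sloreta_standardize(J, source_model, alpha)
  rts <- parcellate(sqrt(pw), source_model$parcellation,
                    recording$ez_regions)
  new_recording(
    patient_id = recording$patient_id, modality = "scalp",
    state = recording$state, data = rts$data,
    sampling_rate = recording$sampling_rate,
    channel_labels = rownames(rts$data),
    ez_mask = rts$ez_region_mask,
    ez_regions = recording$ez_regions,
    provenance = c(recording$provenance, list(esi = TRUE))
  )
}
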