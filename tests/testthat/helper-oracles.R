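# Independent brute-force oracles used to validate the package
# implementations. These deliberately use different algorithms from the
# package code paths (path enumeration and Floyd-Warshall instead of
# Brandes/BFS, explicit sign enumeration instead of convolution).

rand_adjacency <- function(n, p = 0.4) {
  a <- matrix(0L, n, n)
  up <- upper.tri(a)
  a[up] <- rbinom(sum(up), 1, p)
  a <- a + t(a)
  dimnames(a) <- list(paste0("N", 1:n), paste0("N", 1:n))
  a
}

# All-pairs geodesics by Floyd-Warshall (not BFS).
oracle_distances <- function(a) {
  n <- nrow(a)
  D <- matrix(Inf, n, n)
  D[a == 1] <- 1
  diag(D) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

# Shortest-path counts sigma_st by dynamic programming on distances.
oracle_path_counts <- function(a, D = oracle_distances(a)) {
  n <- nrow(a)
  S <- matrix(0, n, n)
  diag(S) <- 1
  for (s in 1:n) {
    ord <- order(D[s, ])
    for (t in ord) {
      if (t == s || !is.finite(D[s, t])) next
      pred <- which(a[, t] == 1 & D[s, ] == D[s, t] - 1)
      S[s, t] <- sum(S[s, pred])
    }
  }
  S
}

oracle_betweenness <- function(a) {
  n <- nrow(a)
  D <- oracle_distances(a)
  S <- oracle_path_counts(a, D)
  bc <- numeric(n)
  for (i in 1:n) {
    for (s in 1:(n - 1)) for (t in (s + 1):n) {
      if (s == i || t == i || !is.finite(D[s, t])) next
      if (is.finite(D[s, i]) && is.finite(D[i, t]) &&
          D[s, i] + D[i, t] == D[s, t]) {
        bc[i] <- bc[i] + S[s, i] * S[i, t] / S[s, t]
      }
    }
  }
  bc
}

oracle_clustering <- function(a) {
  n <- nrow(a)
  sapply(1:n, function(i) {
    nb <- which(a[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    e <- 0
    for (x in seq_along(nb)) for (y in seq_along(nb)) {
      if (x < y && a[nb[x], nb[y]] == 1) e <- e + 1
    }
    2 * e / (k * (k - 1))
  })
}

oracle_local_efficiency <- function(a) {
  n <- nrow(a)
  sapply(1:n, function(i) {
    nb <- which(a[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    D <- oracle_distances(a[nb, nb, drop = FALSE])
    tot <- 0
    for (x in seq_len(k)) for (y in seq_len(k)) {
      if (x != y && is.finite(D[x, y])) tot <- tot + 1 / D[x, y]
    }
    tot / (k * (k - 1))
  })
}

# Exact two-sided signed-rank p by full 2^n enumeration over sign
# assignments of the observed (possibly tied) ranks.
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  n_le <- 0; n_ge <- 0
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    W <- sum(r[signs])
    if (W <= W_obs + 1e-12) n_le <- n_le + 1
    if (W >= W_obs - 1e-12) n_ge <- n_ge + 1
  }
  min(1, 2 * min(n_le, n_ge) / 2^n)
}

# Small SEEG cohorts are expensive to simulate; build once per test run.
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort_features <- function(key, builder) {
  if (!exists(key, envir = .cohort_cache)) {
    assign(key, builder(), envir = .cohort_cache)
  }
  get(key, envir = .cohort_cache)
}

# A reduced-scale SEEG cohort configuration used by unit tests (fewer,
# shorter channels than the study-scale defaults so the suite stays fast;
# coupling structure and gain heterogeneity are the package defaults).
test_seeg_config <- function(state = "interictal", n_patients = 10,
                             seed = 42, ...) {
  simulation_config(
    "seeg", state, n_patients = n_patients,
    channels_mean = 40, channels_sd = 6, epoch_length = 4,
    sampling_rate = 500, seed = seed, ...
  )
}

cohort_feature_table <- function(cfg) {
  do.call(rbind, lapply(seq_len(cfg$n_patients), function(p) {
    rec <- if (cfg$modality == "seeg") simulate_seeg(cfg, patients = p)[[1]]
    network_features(rec)$features
  }))
}
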