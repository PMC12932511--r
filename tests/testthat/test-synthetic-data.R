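# Synthetic cohort generator.

test_that("configuration is validated", {
  expect_error(simulation_config(coupling = list(c_intra_nez = 1.2,
                                                 c_intra_ez = 0.5,
                                                 c_cross = 0.2)), "coupling")
  expect_error(simulation_config(noise_sd = 0), "noise_sd")
  expect_error(simulation_config(epoch_length = 0.0003), "integer")
  expect_error(simulation_config("scalp", ez_amp_ratio = 0.8), "dominate")
  cfg <- simulation_config("seeg")
  expect_equal(cfg$sampling_rate, 2000)
  expect_equal(cfg$patient_gain_cv, 0.4)
  cfgs <- simulation_config("scalp")
  expect_equal(cfgs$sampling_rate, 500)
  expect_equal(cfgs$patient_gain_cv, 0.16)
  expect_equal(cfgs$ez_count_range, c(5L, 31L))
})

test_that("recordings are reproducible and structurally valid", {
  cfg <- test_seeg_config(n_patients = 2)
  r1 <- simulate_seeg(cfg)
  r2 <- simulate_seeg(cfg)
  expect_identical(r1[[1]]$data, r2[[1]]$data)        # bit-identical
  expect_identical(r1[[2]]$ez_mask, r2[[2]]$ez_mask)
  # subsetting patients reproduces the full-cohort draw
  expect_identical(simulate_seeg(cfg, patients = 2)[[1]]$data, r2[[2]]$data)
  for (r in r1) {
    expect_true(all(is.finite(r$data)))
    expect_equal(length(r$ez_mask), nrow(r$data))
    expect_true(any(r$ez_mask) && any(!r$ez_mask))
    expect_true(sum(r$ez_mask) >= 8 && sum(r$ez_mask) <= 30)
  }
})

test_that("interictal default yields EZ degree below NEZ in every band", {
  ft <- cached_cohort_features("seeg_small", function() {
    cohort_feature_table(test_seeg_config())
  })
  ez <- ft$ez_label == "EZ"
  for (b in c("full", "delta", "theta", "alpha", "beta", "gamma", "hf")) {
    col <- paste0(b, "_nd")
    expect_lt(mean(ft[[col]][ez]), mean(ft[[col]][!ez]))
  }
})

test_that("EZ-NEZ degree contrast survives the threshold sweep", {
  cfg <- test_seeg_config(n_patients = 4)
  ok <- vapply(c(0.6, 0.7, 0.8), function(tt) {
    ft <- do.call(rbind, lapply(1:4, function(p) {
      network_features(simulate_seeg(cfg, patients = p)[[1]],
                       threshold = tt)$features
    }))
    mean(ft$full_nd[ft$ez_label == "EZ"]) <
      mean(ft$full_nd[ft$ez_label == "NEZ"])
  }, logical(1))
  expect_true(all(ok))
})

test_that("EZ internal density decreases with the EZ internal coupling", {
  grid <- c(0.3, 0.55, 0.8)
  mean_dez <- vapply(grid, function(e_intra) {
    d <- numeric(0)
    for (s in 1:6) {
      cfg <- test_seeg_config(
        n_patients = 1, seed = 100 + s,
        coupling = list(c_intra_nez = 0.9, c_intra_ez = e_intra,
                        c_cross = 0.2))
      nf <- network_features(simulate_seeg(cfg, patients = 1)[[1]],
                             band_defs = band_set(500, "full"))
      d <- c(d, nf$densities$d_ez)
    }
    mean(d)
  }, numeric(1))
  expect_true(all(diff(mean_dez) > 0))   # density rises with coupling
})

test_that("ictal state surges the configured bands only", {
  mean_density <- function(state, band) {
    cfg <- test_seeg_config(state = state, n_patients = 3, seed = 77)
    d <- do.call(rbind, lapply(1:3, function(p) {
      network_features(simulate_seeg(cfg, patients = p)[[1]])$densities
    }))
    colMeans(d[d$band == band, c("d_ez", "d_nez", "d_cross")])
  }
  for (b in c("gamma", "hf")) {
    ict <- mean_density("ictal", b)
    inter <- mean_density("interictal", b)
    expect_true(all(ict > inter))
  }
  # delta: EZ internal coupling boost without a hypersynchrony surge
  ict_d <- mean_density("ictal", "delta")
  inter_d <- mean_density("interictal", "delta")
  expect_gt(ict_d["d_ez"], inter_d["d_ez"])
})

test_that("scalp simulation is reproducible and EZ-driver dominated", {
  sm <- build_source_model(n_regions = 24, sources_per_region = 1,
                           seed = 10)
  cfg <- simulation_config("scalp", n_patients = 1, epoch_length = 2,
                           ez_count_range = c(1, 1), noise_sd = 1e-4,
                           ez_amp_ratio = 8, seed = 5)
  r1 <- simulate_scalp(cfg, sm)[[1]]
  r2 <- simulate_scalp(cfg, sm)[[1]]
  expect_identical(r1$data, r2$data)
  expect_equal(nrow(r1$data), 16L)
  expect_length(r1$ez_regions, 1L)
  # the electrode with maximal variance is the one the forward model
  # predicts for the EZ dipole (radial moment at the EZ source)
  src_idx <- which(sm$parcellation == r1$ez_regions)
  ori <- sm$sources[src_idx, ] / sqrt(sum(sm$sources[src_idx, ]^2))
  gain <- abs(sm$K[, (3 * src_idx - 2):(3 * src_idx)] %*% ori)
  expect_equal(unname(which.max(apply(r1$data, 1, var))),
               unname(which.max(gain)))
})

test_that("scalp recordings flow through source imaging with region labels", {
  sm <- build_source_model(n_regions = 24, sources_per_region = 1, seed = 10)
  cfg <- simulation_config("scalp", n_patients = 1, epoch_length = 2,
                           ez_count_range = c(3, 5), seed = 8)
  rec <- simulate_scalp(cfg, sm)[[1]]
  img <- source_image(rec, sm)
  expect_equal(nrow(img$data), 24L)
  expect_equal(sum(img$ez_mask), length(rec$ez_regions))
  # EZ parcels should carry more reconstructed power than NEZ parcels
  v <- apply(img$data, 1, var)
  expect_gt(mean(v[img$ez_mask]), mean(v[!img$ez_mask]))
})
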