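# Class balancing, preprocessing, nested grouped CV and permutation test.

toy_table <- function(n_per_patient = c(P1 = 40, P2 = 30, P3 = 30),
                      ez_frac = 0.3, sep = 3, noise_sd = 1, seed = 1) {
  set.seed(seed)
  rows <- lapply(names(n_per_patient), function(p) {
    n <- n_per_patient[[p]]
    ez <- rep(c("EZ", "NEZ"), c(round(ez_frac * n), n - round(ez_frac * n)))
    data.frame(patient_id = p, node = paste0(p, "_", seq_len(n)),
               state = "interictal", modality = "seeg", ez_label = ez,
               f1 = rnorm(n, sd = noise_sd) + ifelse(ez == "EZ", 0, sep),
               f2 = rnorm(n, sd = noise_sd) + ifelse(ez == "EZ", 0, sep / 2))
  })
  do.call(rbind, rows)
}

test_that("balancing undersamples to 1:1, proportionally by patient", {
  tab <- toy_table(c(P1 = 100, P2 = 60, P3 = 40), ez_frac = 0.3)
  bal <- balance_classes(tab, seed = 3)
  expect_equal(unname(table(bal$ez_label)["EZ"]),
               unname(table(bal$ez_label)["NEZ"]))
  expect_equal(sum(bal$ez_label == "EZ"), sum(tab$ez_label == "EZ"))
  # per-patient NEZ retention proportional to that patient's NEZ share
  tot_nez <- table(tab$patient_id[tab$ez_label == "NEZ"])
  kept_nez <- table(bal$patient_id[bal$ez_label == "NEZ"])
  target <- sum(tab$ez_label == "EZ") * as.numeric(tot_nez) / sum(tot_nez)
  expect_true(all(abs(as.numeric(kept_nez) - target) <= 1))
  # already balanced tables pass through unchanged
  even <- toy_table(c(P1 = 40), ez_frac = 0.5)
  expect_identical(balance_classes(even, seed = 1), even)
})

test_that("log + Z transform standardizes train and never leaks", {
  x <- matrix(c(0, exp(1) - 1), 2, 1)
  z <- log_z_transform(x)
  expect_equal(mean(z), 0)
  # logs are {0, 1}; centering and scaling gives +/- 0.5 / sd({0, 1})
  expect_equal(as.numeric(z), c(-0.5, 0.5) / stats::sd(c(0, 1)))
  set.seed(4)
  train <- matrix(rexp(200), 50, 4)
  zt <- log_z_transform(train)
  expect_lt(max(abs(colMeans(zt))), 1e-9)
  expect_equal(unname(apply(zt, 2, stats::sd)), rep(1, 4), tolerance = 1e-9)
  # test set transformed with train statistics keeps its shift
  test <- train + 5
  zte <- log_z_transform(train, test)
  expect_true(all(colMeans(zte) > 0.5))
  expect_warning(log_z_transform(cbind(train, 1)), "zero-variance")
  expect_error(log_z_transform(matrix(-1, 2, 2)), "non-negative")
})

test_that("score metrics match hand counts", {
  m <- evaluate_scores(c("EZ", "EZ", "NEZ", "NEZ"), c(0.9, 0.8, 0.3, 0.2))
  expect_equal(m$auc, 1)
  expect_equal(m$accuracy, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  m2 <- evaluate_scores(c("EZ", "NEZ", "EZ", "NEZ"), c(0.9, 0.8, 0.3, 0.2))
  expect_equal(m2$auc, 0.75)          # 3 of 4 concordant pairs
  m3 <- evaluate_scores(c("EZ", "NEZ"), c(0.5, 0.5))
  expect_equal(m3$auc, 0.5)           # ties counted half
  expect_equal(evaluate_scores(c("EZ", "EZ"), c(0.2, 0.9))$flag,
               "single_class")
})

test_that("AUC rank statistic agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(14)
  lab <- sample(c("EZ", "NEZ"), 60, replace = TRUE)
  sc <- runif(60)
  ours <- evaluate_scores(lab, sc)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(lab == "EZ", sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("separable features give perfect pooled metrics for every model", {
  # EZ features identically 0, NEZ identically 10 (no noise)
  tab <- toy_table(c(P1 = 30, P2 = 30, P3 = 30, P4 = 30, P5 = 30),
                   sep = 10, noise_sd = 0, seed = 2)
  # Z-scoring inside the pipeline for the scale-sensitive models, as in the
  # study protocol; trees ignore it either way
  for (mod in c("svm", "rf", "gbm", "knn", "lr")) {
    rep_ <- nested_group_cv(tab, mod, preprocessing = "z", seed = 11)
    expect_equal(rep_$auc, 1, tolerance = 1e-9)
    expect_gte(rep_$accuracy, 0.95)
  }
})

test_that("no patient crosses an outer train/test boundary", {
  tab <- toy_table(c(P1 = 30, P2 = 25, P3 = 30, P4 = 20, P5 = 30,
                     P6 = 25, P7 = 20), sep = 2, seed = 3)
  rep_ <- nested_group_cv(tab, "lr", seed = 5)
  for (a in rep_$fold_audit) {
    expect_length(intersect(a$train_patients, a$test_patients), 0L)
  }
  test_sets <- unlist(lapply(rep_$fold_audit, function(a) a$test_patients))
  expect_setequal(test_sets, unique(tab$patient_id))  # each tested once
  expect_equal(anyDuplicated(test_sets), 0L)
  expect_error(nested_group_cv(toy_table(c(P1 = 30, P2 = 30)), "lr"),
               "patients")
})

test_that("identical seeds reproduce identical reports", {
  tab <- toy_table(c(P1 = 24, P2 = 24, P3 = 24, P4 = 24, P5 = 24),
                   sep = 1.2, seed = 6)
  for (mod in c("svm", "rf", "knn", "lr", "gbm")) {
    r1 <- nested_group_cv(tab, mod, seed = 21)
    r2 <- nested_group_cv(tab, mod, seed = 21)
    expect_identical(r1$scores, r2$scores)
    expect_identical(r1$fold_params, r2$fold_params)
  }
})

test_that("permutation p has an add-one floor and detects signal", {
  tab <- toy_table(c(P1 = 20, P2 = 20, P3 = 20, P4 = 20, P5 = 20),
                   sep = 20, seed = 7)
  pt <- permutation_test(tab, "knn", n_perm = 19, seed = 2)
  expect_equal(pt$observed, 1)
  expect_equal(pt$p, 1 / 20)          # beats every null draw
  expect_gt(pt$p, 0)
  expect_length(pt$null, 19L)
  expect_error(permutation_test(tab, "knn", n_perm = 0), "n_perm")
})
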