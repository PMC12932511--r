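## Patient-grouped machine-learning validation of the nodal features.
## The protocol is a nested cross-validation: an outer Group K-Fold over
## patients estimates generalization to unseen subjects, and an inner
## grouped 3-fold grid search tunes hyperparameters by AUC inside each
## training fold. All preprocessing statistics (log + Z) are fitted on
## training rows only.

#' Cross-validation protocol
#'
#' @param outer_k Outer group-fold count (patients per fold held out
#'   together; default 5).
#' @param inner_k Inner grouped folds for the grid search (default 3).
#' @param grids Named list of hyperparameter grids (data.frames) per model;
#'   defaults: SVM `cost` 0.1/1/10; RF `num_trees` 50/100/200 x `max_depth`
#'   unlimited/10/20; GBM `nrounds` 50/100/200 x `eta` 0.05/0.1; KNN `k`
#'   3/5/7/9/11; LR ridge inverse penalty `C` 0.1/1/10.
#' @return A `cv_protocol` list.
#' @export
cv_protocol <- function(outer_k = 5L, inner_k = 3L, grids = default_grids()) {
  structure(list(outer_k = as.integer(outer_k), inner_k = as.integer(inner_k),
                 grids = grids, scoring = "auc"),
            class = "cv_protocol")
}

default_grids <- function() {
  list(
    svm = data.frame(cost = c(0.1, 1, 10)),
    rf = expand.grid(num_trees = c(50, 100, 200), max_depth = c(0, 10, 20)),
    gbm = expand.grid(nrounds = c(50, 100, 200), eta = c(0.05, 0.1)),
    knn = data.frame(k = c(3, 5, 7, 9, 11)),
    lr = data.frame(C = c(0.1, 1, 10))
  )
}

# Models whose scores depend on feature scale; trees are left on the
# original feature space.
scaled_models <- c("svm", "knn", "lr")

# Coerce a nodal feature table into the ML layout: label (factor NEZ/EZ,
# EZ positive), group (patient), feature matrix.
as_ml_table <- function(table) {
  if (!is.null(table$ez_label) && is.null(table$label))
    table$label <- table$ez_label
  if (!is.null(table$patient_id) && is.null(table$group))
    table$group <- table$patient_id
  if (is.null(table$label) || is.null(table$group))
    stopf("table needs label/ez_label and group/patient_id columns")
  feat <- feature_columns(table)
  x <- as.matrix(table[, feat, drop = FALSE])
  if (!is.numeric(x)) stopf("non-numeric feature columns")
  list(x = x, y = factor(table$label, levels = c("NEZ", "EZ")),
       group = as.character(table$group), features = feat)
}

#' Balance classes by stratified undersampling
#'
#' Randomly undersamples the majority class (without replacement) to a
#' strict 1:1 ratio, allocating retained rows to patients proportionally to
#' each patient's share of the majority class (largest-remainder rounding),
#' so the group structure survives balancing.
#'
#' @param table Nodal feature table (or any table with `ez_label`/`label`
#'   and `patient_id`/`group`).
#' @param seed Integer seed.
#' @return The balanced table (original row order preserved).
#' @export
balance_classes <- function(table, seed = 1L) {
  ml <- as_ml_table(table)
  y <- ml$y
  if (any(table(y) == 0)) stopf("both classes must be present")
  n_by <- table(y)
  if (n_by[1] == n_by[2]) return(table)
  minority <- names(n_by)[which.min(n_by)]
  majority <- setdiff(levels(y), minority)
  target <- min(n_by)
  maj_idx <- which(y == majority)
  grp <- ml$group[maj_idx]
  counts <- table(grp)
  quota <- target * as.numeric(counts) / length(maj_idx)
  base <- floor(quota)
  rem <- target - sum(base)
  frac_order <- order(quota - base, decreasing = TRUE)
  base[frac_order[seq_len(rem)]] <- base[frac_order[seq_len(rem)]] + 1
  keep_maj <- with_seed(seed, {
    unlist(lapply(seq_along(counts), function(i) {
      rows <- maj_idx[grp == names(counts)[i]]
      sample(rows, min(base[i], length(rows)))
    }))
  })
  # largest-remainder can under-fill when a patient has fewer rows than its
  # quota; top up from the remaining pool
  if (length(keep_maj) < target) {
    pool <- setdiff(maj_idx, keep_maj)
    keep_maj <- c(keep_maj, with_seed(seed + 1L,
                                      sample(pool, target - length(keep_maj))))
  }
  keep <- sort(c(which(y == minority), keep_maj))
  table[keep, , drop = FALSE]
}

#' Log + Z feature transform
#'
#' `x -> log(1 + x)` to deflate the heavy right tail of count-like nodal
#' metrics (degree and betweenness can be exactly zero, hence `log1p`),
#' followed by Z-scoring with mean and standard deviation estimated on the
#' training rows only. Zero-variance training columns are centred and left
#' at zero.
#'
#' @param train Training feature matrix (rows x features, all >= 0).
#' @param newdata Matrix to transform with the training statistics
#'   (defaults to `train`).
#' @param method `"log_z"`, `"z"`, or `"none"`.
#' @return Transformed `newdata`, with the fitted statistics in attributes
#'   `"mu"` and `"sigma"`.
#' @export
log_z_transform <- function(train, newdata = train,
                            method = c("log_z", "z", "none")) {
  method <- match.arg(method)
  pp <- fit_preproc(train, method)
  apply_preproc(pp, newdata)
}

fit_preproc <- function(train, method) {
  do_log <- method %in% c("log_z", "log")
  do_z <- method %in% c("log_z", "z")
  if (do_log && any(train < 0))
    stopf("log transform requires non-negative features")
  tr <- if (do_log) log1p(train) else train
  mu <- sig <- NULL
  if (do_z) {
    mu <- colMeans(tr)
    sig <- apply(tr, 2, stats::sd)
    if (any(sig < .Machine$double.eps)) {
      warnf("%d zero-variance training column(s); set to 0 after centering",
            sum(sig < .Machine$double.eps))
      sig[sig < .Machine$double.eps] <- 1
    }
  }
  list(do_log = do_log, do_z = do_z, mu = mu, sigma = sig)
}

apply_preproc <- function(pp, x) {
  if (pp$do_log) x <- log1p(x)
  if (pp$do_z) x <- sweep(sweep(x, 2, pp$mu), 2, pp$sigma, "/")
  attr(x, "mu") <- pp$mu
  attr(x, "sigma") <- pp$sigma
  x
}

# ---- model registry ------------------------------------------------------

fit_model <- function(name, x, y, params) {
  switch(name,
    svm = e1071::svm(x, y, kernel = "radial", cost = params$cost,
                     scale = FALSE),
    rf = ranger::ranger(
      x = as.data.frame(x), y = y, num.trees = params$num_trees,
      max.depth = params$max_depth, probability = TRUE,
      num.threads = 1, seed = sample.int(1e6, 1)),
    gbm = xgboost::xgboost(
      x, y, nrounds = params$nrounds, learning_rate = params$eta,
      nthreads = 1, seed = sample.int(1e6, 1)),
    knn = list(x = x, y = y, k = params$k),
    lr = {
      # glmnet requires >= 2 columns; pad degenerate tables with a constant.
      # C is the inverse penalty strength; glmnet's lambda is scaled per
      # observation, so lambda = 1 / (C n).
      if (ncol(x) < 2) x <- cbind(x, .pad = 0)
      m <- suppressWarnings(glmnet::glmnet(
        x, y, family = "binomial", alpha = 0,
        lambda = 1 / (params$C * nrow(x))))
      attr(m, "padded") <- ncol(x) == 2 && colnames(x)[2] == ".pad"
      m
    },
    stopf("unknown model '%s'", name)
  )
}

# P(EZ) score in [0, 1] for each row of x.
predict_score <- function(name, model, x) {
  switch(name,
    svm = {
      dvm <- attr(stats::predict(model, x, decision.values = TRUE),
                  "decision.values")
      dv <- dvm[, 1]
      # positive decision values point at the first class in the pair label
      if (!startsWith(colnames(dvm)[1], "EZ")) dv <- -dv
      stats::plogis(dv)
    },
    rf = stats::predict(model, data = as.data.frame(x))$predictions[, "EZ"],
    gbm = as.numeric(stats::predict(model, x)),  # P(second level) = P(EZ)
    knn = {
      pr <- class::knn(model$x, x, model$y, k = model$k, prob = TRUE)
      votes <- attr(pr, "prob")
      ifelse(pr == "EZ", votes, 1 - votes)
    },
    lr = {
      if (isTRUE(attr(model, "padded"))) x <- cbind(x, .pad = 0)
      stats::predict(model, x, type = "response")[, 1]
    },
    stopf("unknown model '%s'", name)
  )
}

#' Classification metrics from scores
#'
#' AUC by the rank statistic (ties counted half) plus the confusion-matrix
#' metrics at a probability threshold.
#'
#' @param labels Factor/character with positive class `"EZ"`, or logical.
#' @param scores Numeric P(EZ) scores in \[0, 1\].
#' @param threshold Decision threshold (default 0.5).
#' @return List: `auc`, `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, `f1`, `confusion` (2 x 2), `flag`.
#' @export
evaluate_scores <- function(labels, scores, threshold = 0.5) {
  pos <- if (is.logical(labels)) labels else labels == "EZ"
  n1 <- sum(pos)
  n0 <- sum(!pos)
  flag <- NA_character_
  auc <- if (n1 == 0 || n0 == 0) {
    flag <- "single_class"
    NA_real_
  } else {
    r <- rank(scores)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  pred <- scores >= threshold
  tp <- sum(pred & pos); fn <- sum(!pred & pos)
  tn <- sum(!pred & !pos); fp <- sum(pred & !pos)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  sens <- if (n1 > 0) tp / n1 else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  list(auc = auc,
       accuracy = (tp + tn) / length(scores),
       sensitivity = sens,
       specificity = if (n0 > 0) tn / n0 else NA_real_,
       precision = prec, f1 = f1,
       confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                          dimnames = list(pred = c("EZ", "NEZ"),
                                          truth = c("EZ", "NEZ"))),
       flag = flag)
}

# Balanced group K-fold: patients shuffled, then greedily assigned (largest
# first) to the currently smallest fold. Returns a fold index per row.
group_kfold <- function(groups, k, seed = NULL) {
  ug <- unique(groups)
  if (length(ug) < k)
    stopf("only %d patients for %d folds", length(ug), k)
  counts <- table(groups)[ug]
  ord <- with_seed(seed, sample(seq_along(ug)))
  ug <- ug[ord]; counts <- counts[ord]
  ug <- ug[order(counts, decreasing = TRUE)]
  counts <- sort(counts, decreasing = TRUE)
  fold_of <- integer(length(ug))
  load <- numeric(k)
  for (i in seq_along(ug)) {
    f <- which.min(load)
    fold_of[i] <- f
    load[f] <- load[f] + counts[i]
  }
  fold_of[match(groups, ug)]
}

#' Nested patient-grouped cross-validation
#'
#' Outer Group K-Fold by patient; within each outer training fold an inner
#' grouped K-fold grid search selects the hyperparameters with the highest
#' mean inner AUC, the model is refitted on the full outer-training fold and
#' scored on the held-out patients. Test-fold scores are pooled over all
#' outer folds before computing metrics. Scaling statistics (and the log + Z
#' transform) are fitted on training rows only; tree models (RF, GBM) skip
#' the Z step and keep the original feature space.
#'
#' @param table Nodal feature table (see [as_ml_table()] conventions).
#' @param model_name One of `"svm"`, `"rf"`, `"gbm"`, `"knn"`, `"lr"`.
#' @param protocol A [cv_protocol()].
#' @param preprocessing `"none"`, `"z"`, or `"log_z"`.
#' @param seed Integer seed controlling fold assignment and stochastic
#'   fitters.
#' @return An `ez_classifier_report`: pooled metrics, per-fold chosen
#'   hyperparameters, fold membership audit, pooled scores and labels.
#' @export
nested_group_cv <- function(table, model_name = "svm",
                            protocol = cv_protocol(),
                            preprocessing = c("none", "z", "log_z"),
                            seed = 1L) {
  preprocessing <- match.arg(preprocessing)
  ml <- as_ml_table(table)
  grid <- protocol$grids[[model_name]]
  if (is.null(grid)) stopf("no grid for model '%s'", model_name)
  eff_method <- effective_preproc(preprocessing, model_name)
  with_seed(seed, {
    folds <- group_kfold(ml$group, protocol$outer_k)
    pooled_scores <- numeric(0)
    pooled_labels <- character(0)
    fold_params <- list()
    fold_audit <- list()
    for (f in seq_len(protocol$outer_k)) {
      tr <- folds != f
      te <- !tr
      if (length(unique(ml$y[tr])) < 2L)
        stopf("outer training fold %d has a single class", f)
      best <- select_params(ml$x[tr, , drop = FALSE], ml$y[tr],
                            ml$group[tr], model_name, grid,
                            protocol$inner_k, eff_method)
      pp <- fit_preproc(ml$x[tr, , drop = FALSE], eff_method)
      xtr <- apply_preproc(pp, ml$x[tr, , drop = FALSE])
      xte <- apply_preproc(pp, ml$x[te, , drop = FALSE])
      model <- fit_model(model_name, xtr, ml$y[tr], best)
      pooled_scores <- c(pooled_scores, predict_score(model_name, model, xte))
      pooled_labels <- c(pooled_labels, as.character(ml$y[te]))
      fold_params[[f]] <- best
      fold_audit[[f]] <- list(train_patients = unique(ml$group[tr]),
                              test_patients = unique(ml$group[te]))
    }
    metrics <- evaluate_scores(pooled_labels, pooled_scores)
    structure(c(metrics,
                list(model = model_name, preprocessing = preprocessing,
                     fold_params = fold_params, fold_audit = fold_audit,
                     scores = pooled_scores, labels = pooled_labels,
                     seed = seed)),
              class = "ez_classifier_report")
  })
}

effective_preproc <- function(preprocessing, model_name) {
  if (model_name %in% scaled_models) return(preprocessing)
  switch(preprocessing, log_z = "log", z = "none", preprocessing)
}

# Inner grouped grid search; returns the grid row with best mean AUC.
select_params <- function(x, y, group, model_name, grid, inner_k, eff_method) {
  if (nrow(grid) == 1L) return(grid[1, , drop = FALSE])
  k <- min(inner_k, length(unique(group)))
  ifolds <- group_kfold(group, k)
  score <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    aucs <- numeric(0)
    for (f in seq_len(k)) {
      tr <- ifolds != f
      if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) next
      pp <- fit_preproc(x[tr, , drop = FALSE], eff_method)
      xtr <- apply_preproc(pp, x[tr, , drop = FALSE])
      xte <- apply_preproc(pp, x[!tr, , drop = FALSE])
      m <- fit_model(model_name, xtr, y[tr], grid[gi, , drop = FALSE])
      s <- predict_score(model_name, m, xte)
      aucs <- c(aucs, evaluate_scores(y[!tr], s)$auc)
    }
    score[gi] <- if (length(aucs)) mean(aucs) else -Inf
  }
  grid[which.max(score), , drop = FALSE]
}

#' @export
print.ez_classifier_report <- function(x, ...) {
  cat(sprintf(
    "<ez_classifier_report> %s (%s)\n  AUC %.3f | acc %.3f | sens %.3f | spec %.3f | prec %.3f | F1 %.3f\n",
    toupper(x$model), x$preprocessing, x$auc, x$accuracy, x$sensitivity,
    x$specificity, x$precision, x$f1))
  invisible(x)
}

#' Permutation test of classifier performance
#'
#' Reruns the full nested cross-validation on label permutations of the
#' pooled table and compares the observed AUC against the null AUC
#' distribution. The p-value uses add-one smoothing,
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`, so it can never be 0.
#'
#' @inheritParams nested_group_cv
#' @param n_perm Number of label permutations (study default 1000).
#' @return List: `observed` (AUC), `null` (length `n_perm`), `p`, and the
#'   observed `report`.
#' @export
permutation_test <- function(table, model_name = "svm",
                             protocol = cv_protocol(),
                             preprocessing = c("none", "z", "log_z"),
                             n_perm = 1000L, seed = 1L) {
  preprocessing <- match.arg(preprocessing)
  if (n_perm < 1) stopf("n_perm must be >= 1")
  report <- nested_group_cv(table, model_name, protocol, preprocessing, seed)
  lbl_col <- if (!is.null(table$label)) "label" else "ez_label"
  null_auc <- vapply(seq_len(n_perm), function(b) {
    perm <- table
    perm[[lbl_col]] <- with_seed(seed + b, sample(perm[[lbl_col]]))
    nested_group_cv(perm, model_name, protocol, preprocessing, seed)$auc
  }, numeric(1))
  p <- (1 + sum(null_auc >= report$auc)) / (1 + n_perm)
  list(observed = report$auc, null = null_auc, p = p, report = report)
}
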