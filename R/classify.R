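# Diagnostic pipeline: random-forest feature ranking, radial-kernel SVM
# over ranked feature subsets in stratified cross-validation, ROC analysis
# at the optimal operating point, and a final model fitted on all samples.

#' Rank features by random-forest importance
#'
#' Impurity-based importances from an ensemble of `n_trees` randomized
#' trees, normalized to sum to 1. Ties are broken by lower feature index;
#' results are deterministic for a fixed seed.
#'
#' @param X Numeric feature matrix (samples x features).
#' @param y Binary labels (0/1), at least two samples per class.
#' @param n_trees Number of trees (default 1000).
#' @param rng_seed Seed for the forest.
#' @return List of class `feature_ranking` with `order` (feature indices,
#'   most important first) and `importances` (non-negative, sum 1).
#' @export
rank_features_rf <- function(X, y, n_trees = 1000, rng_seed = 1) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("`y` must contain both classes",
                                  call. = FALSE)
  df <- as.data.frame(X)
  names(df) <- sprintf("f%05d", seq_len(ncol(X)))
  rf <- ranger::ranger(x = df, y = factor(y, levels = c(0, 1)),
                       num.trees = n_trees, importance = "impurity",
                       seed = rng_seed, num.threads = 1)
  imp <- pmax(unname(rf$variable.importance), 0)
  total <- sum(imp)
  imp <- if (total > 0) imp / total else rep(1 / length(imp), length(imp))
  structure(list(order = order(-imp, seq_along(imp)), importances = imp),
            class = "feature_ranking")
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin over folds.
stratified_folds <- function(y, k, rng_seed) {
  fold <- integer(length(y))
  with_rng(rng_seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Column-wise standardization constants from training data (sd 0 -> 1 so
# constant columns map to 0).
scale_constants <- function(X) {
  m <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  s[!is.finite(s) | s == 0] <- 1
  list(center = m, scale = s)
}

apply_scale <- function(X, sc) {
  sweep(sweep(X, 2, sc$center, "-"), 2, sc$scale, "/")
}

# Fit a radial SVM and return a scorer whose output increases with the
# probability of class 1 (e1071's decision-value sign depends on the class
# order seen in training, so orientation is fixed against training scores).
fit_radial_svm <- function(X, y, C, gamma) {
  fit <- e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "radial",
                    gamma = gamma, cost = C, scale = FALSE)
  tr <- as.numeric(attr(stats::predict(fit, X, decision.values = TRUE),
                        "decision.values"))
  flip <- mean(tr[y == 1]) < mean(tr[y == 0])
  list(fit = fit, flip = flip)
}

svm_scores <- function(model, X) {
  s <- as.numeric(attr(stats::predict(model$fit, X, decision.values = TRUE),
                       "decision.values"))
  if (model$flip) -s else s
}

# Trapezoid AUC of scores against 0/1 labels (higher score = class 1).
score_auc <- function(scores, y) {
  r <- roc_analysis(scores, y)
  r$auc
}

#' Cross-validated AUC profile over feature counts and C values
#'
#' Stratified k-fold cross-validation. Within each training fold the
#' features are standardized and ranked by random forest; for each
#' candidate feature count and each `C`, a radial SVM with
#' `gamma = 1/n_features` is fitted on the top-ranked features and scored
#' by AUC on the held-out fold. Ranking inside the fold prevents
#' feature-selection leakage into the test fold.
#'
#' @param X Feature matrix (samples x features).
#' @param y Binary labels (0/1).
#' @param C_grid Candidate SVM cost values (default 1, 10, 100).
#' @param n_features_grid Candidate feature counts; default a log-spaced
#'   subsample of 1..ncol(X).
#' @param k_folds Number of folds (default 10; must not exceed the smaller
#'   class count).
#' @param n_trees Trees for the per-fold ranking forest.
#' @param rng_seed Seed for folds and forests.
#' @return Tibble of class `performance_profile`: `C`, `n_features`,
#'   `mean_auc`, `sd_auc`.
#' @export
cv_auc_profile <- function(X, y, C_grid = c(1, 10, 100),
                           n_features_grid = NULL, k_folds = 10,
                           n_trees = 1000, rng_seed = 1) {
  y <- as.integer(y)
  if (k_folds > min(table(y))) {
    stop("`k_folds` must not exceed the smaller class count", call. = FALSE)
  }
  p <- ncol(X)
  if (is.null(n_features_grid)) {
    n_features_grid <- sort(unique(pmin(p, c(
      round(exp(seq(0, log(p), length.out = 15L)))))))
  }
  n_features_grid <- sort(unique(as.integer(n_features_grid)))
  if (any(n_features_grid < 1 | n_features_grid > p)) {
    stop("`n_features_grid` entries must be in 1..ncol(X)", call. = FALSE)
  }
  fold <- stratified_folds(y, k_folds, rng_seed)
  aucs <- array(NA_real_, c(length(C_grid), length(n_features_grid), k_folds))
  for (f in seq_len(k_folds)) {
    tr <- fold != f
    te <- !tr
    if (length(unique(y[te])) < 2 || length(unique(y[tr])) < 2) {
      stop(sprintf("fold %d is degenerate (single-class)", f), call. = FALSE)
    }
    sc <- scale_constants(X[tr, , drop = FALSE])
    Xtr <- apply_scale(X[tr, , drop = FALSE], sc)
    Xte <- apply_scale(X[te, , drop = FALSE], sc)
    rk <- rank_features_rf(Xtr, y[tr], n_trees = n_trees,
                           rng_seed = rng_seed + f)
    for (ni in seq_along(n_features_grid)) {
      keep <- rk$order[seq_len(n_features_grid[ni])]
      for (ci in seq_along(C_grid)) {
        m <- fit_radial_svm(Xtr[, keep, drop = FALSE], y[tr], C_grid[ci],
                            gamma = 1 / n_features_grid[ni])
        aucs[ci, ni, f] <- score_auc(svm_scores(m, Xte[, keep, drop = FALSE]),
                                     y[te])
      }
    }
  }
  out <- expand.grid(C = C_grid, n_features = n_features_grid)
  out$mean_auc <- mapply(function(ci, ni) mean(aucs[ci, ni, ]),
                         match(out$C, C_grid),
                         match(out$n_features, n_features_grid))
  out$sd_auc <- mapply(function(ci, ni) stats::sd(aucs[ci, ni, ]),
                       match(out$C, C_grid),
                       match(out$n_features, n_features_grid))
  structure(tibble::as_tibble(out), class = c("performance_profile",
                                              class(tibble::tibble())))
}

#' Select the best (C, n_features) operating point
#'
#' Argmax of mean AUC; ties broken by smaller feature count, then
#' smaller C.
#'
#' @param profile A [cv_auc_profile()] result.
#' @return List with `C`, `n_features` and `mean_auc`.
#' @export
select_operating_point <- function(profile) {
  if (nrow(profile) == 0) stop("empty performance profile", call. = FALSE)
  ord <- order(-profile$mean_auc, profile$n_features, profile$C)
  best <- profile[ord[1], ]
  list(C = best$C, n_features = best$n_features, mean_auc = best$mean_auc)
}

#' ROC analysis with the closest-to-top-left optimal point
#'
#' Sweeps thresholds over the unique scores (predicting class 1 when
#' `score >= threshold`), computes the ROC curve and trapezoid AUC, and
#' locates the operating point minimizing the Euclidean distance to the
#' ideal point (false-positive rate 0, true-positive rate 1). Sensitivity,
#' specificity and accuracy are reported at that threshold.
#'
#' @param scores Numeric classifier scores (higher = more patient-like).
#' @param y Binary labels (0/1), both classes present.
#' @return List of class `roc_analysis` with `thresholds`, `fpr`, `tpr`,
#'   `auc` and `optimal` (index, threshold, sensitivity, specificity,
#'   accuracy).
#' @export
roc_analysis <- function(scores, y) {
  y <- as.integer(y)
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present",
                                     call. = FALSE)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0) / n_neg,
                numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + tpr[-1]) / 2)
  d2 <- fpr^2 + (1 - tpr)^2
  # ties (within numerical noise) resolve to the highest threshold, i.e.
  # the most specific operating point
  opt <- which(d2 <= min(d2) + 1e-12)[1]
  acc <- vapply(thr, function(t) {
    (sum(scores >= t & y == 1) + sum(scores < t & y == 0)) / length(y)
  }, numeric(1))
  structure(list(
    thresholds = thr, fpr = fpr, tpr = tpr, auc = auc,
    optimal = list(index = opt, threshold = thr[opt],
                   sensitivity = tpr[opt], specificity = 1 - fpr[opt],
                   accuracy = acc[opt])),
    class = "roc_analysis")
}

#' Fit the final classifier on all samples
#'
#' Ranks features on the full data, keeps the top `n_features`,
#' standardizes them, and fits a radial SVM with `gamma = 1/n_features`.
#' The returned model carries the selected indices and scaling constants so
#' it can score new cohorts with matching feature layout (extra unselected
#' columns at prediction time are ignored).
#'
#' @param X Feature matrix.
#' @param y Binary labels (0/1).
#' @param n_features Number of top-ranked features to keep.
#' @param C SVM cost parameter.
#' @param n_trees Trees for the ranking forest.
#' @param rng_seed Seed.
#' @return List of class `trained_classifier`.
#' @export
fit_final_model <- function(X, y, n_features, C, n_trees = 1000,
                            rng_seed = 1) {
  y <- as.integer(y)
  if (n_features > ncol(X)) stop("`n_features` exceeds the feature count",
                                 call. = FALSE)
  ranking <- rank_features_rf(X, y, n_trees = n_trees, rng_seed = rng_seed)
  selected <- ranking$order[seq_len(n_features)]
  sc <- scale_constants(X[, selected, drop = FALSE])
  Xs <- apply_scale(X[, selected, drop = FALSE], sc)
  m <- fit_radial_svm(Xs, y, C, gamma = 1 / n_features)
  structure(list(selected = selected,
                 feature_names = colnames(X)[selected],
                 C = C, gamma = 1 / n_features, scaling = sc,
                 svm = m, ranking = ranking),
            class = "trained_classifier")
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat(sprintf("<trained_classifier> %d features, C = %g, gamma = %.4g\n",
              length(x$selected), x$C, x$gamma))
  invisible(x)
}

#' Score new samples with a trained classifier
#'
#' @param model A [fit_final_model()] result.
#' @param X Feature matrix with the training feature layout (selected
#'   features are picked by index; extra columns are ignored).
#' @return Numeric decision scores (higher = more patient-like).
#' @export
predict_scores <- function(model, X) {
  Xs <- apply_scale(X[, model$selected, drop = FALSE], model$scaling)
  svm_scores(model$svm, Xs)
}

#' Aggregate selected-feature importance per region
#'
#' Sums the importance scores of selected features that refer to the same
#' region and counts how many centrality measures represent it.
#'
#' @param ranking A [rank_features_rf()] result.
#' @param selected Indices of the selected features.
#' @param feature_info Tibble with columns `measure` and `region_label`
#'   aligned with the feature columns (see [cohort_feature_matrix()]), or a
#'   character vector of `measure_regionlabel` names.
#' @return Tibble `region_label`, `importance`, `n_measures`, sorted by
#'   descending importance.
#' @export
region_importance_summary <- function(ranking, selected, feature_info) {
  if (is.character(feature_info)) {
    parts <- regmatches(feature_info,
                        regexpr("_", feature_info), invert = TRUE)
    bad <- vapply(parts, length, integer(1)) != 2
    if (any(bad)) stop("malformed feature names: ",
                       paste(feature_info[bad], collapse = ", "),
                       call. = FALSE)
    feature_info <- tibble::tibble(
      measure = vapply(parts, `[`, character(1), 1),
      region_label = vapply(parts, `[`, character(1), 2))
  }
  if (!all(feature_info$measure %in% MEASURE_ORDER)) {
    stop("unknown measure in feature names", call. = FALSE)
  }
  tibble::tibble(region_label = feature_info$region_label[selected],
                 measure = feature_info$measure[selected],
                 importance = ranking$importances[selected]) |>
    dplyr::group_by(region_label) |>
    dplyr::summarise(importance = sum(importance),
                     n_measures = dplyr::n_distinct(measure),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(importance))
}

#' Share of each centrality measure among selected features
#'
#' @param selected Indices of selected features.
#' @param feature_info As in [region_importance_summary()].
#' @return Tibble `measure`, `percent` (percentages summing to 100).
#' @export
measure_proportions <- function(selected, feature_info) {
  m <- feature_info$measure[selected]
  tab <- table(factor(m, levels = MEASURE_ORDER))
  tibble::tibble(measure = names(tab),
                 percent = 100 * as.numeric(tab) / length(selected))
}
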