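test_that("forest importances rank an informative feature first", {
  set.seed(50)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  hits <- 0L
  for (s in 1:20) {
    set.seed(1000 + s)
    X <- matrix(rnorm(n * 50), n, 50)
    X[, 7] <- y * 4 + rnorm(n, 0, 0.1)  # perfectly separating
    rk <- rank_features_rf(X, y, n_trees = 500, rng_seed = s)
    expect_equal(sum(rk$importances), 1, tolerance = 1e-9)
    expect_true(all(rk$importances >= 0))
    if (rk$order[1] == 7) hits <- hits + 1L
  }
  expect_gte(hits, 19)

  X <- matrix(rnorm(40 * 5), 40, 5)
  r1 <- rank_features_rf(X, rep(c(0, 1), 20), n_trees = 200, rng_seed = 3)
  r2 <- rank_features_rf(X, rep(c(0, 1), 20), n_trees = 200, rng_seed = 3)
  expect_identical(r1, r2)
  expect_error(rank_features_rf(X, rep(0, 40)), "both classes")
})

test_that("cross-validated profiles separate signal from chance", {
  # linearly separable clusters: AUC 1 everywhere
  set.seed(60)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(n * 10), n, 10)
  X[, 1] <- y * 10 + rnorm(n, 0, 0.2)
  prof <- cv_auc_profile(X, y, C_grid = c(1, 100),
                         n_features_grid = c(1, 5, 10), k_folds = 5,
                         n_trees = 200, rng_seed = 1)
  expect_equal(nrow(prof), 6)  # every (C, n) pair present
  expect_true(all(prof$mean_auc == 1))

  # permutation null: grand mean AUC near one half
  means <- vapply(1:10, function(s) {
    set.seed(2000 + s)
    Xn <- matrix(rnorm(80 * 20), 80, 20)
    yn <- sample(rep(c(0, 1), 40))
    pr <- cv_auc_profile(Xn, yn, C_grid = c(1, 10),
                         n_features_grid = c(2, 10), k_folds = 5,
                         n_trees = 100, rng_seed = s)
    mean(pr$mean_auc)
  }, numeric(1))
  expect_lt(abs(mean(means) - 0.5), 0.1)

  expect_error(cv_auc_profile(X, y, k_folds = 25), "class count")
})

test_that("operating-point selection maximizes AUC with sparse ties", {
  one <- tibble::tibble(C = 10, n_features = 4, mean_auc = 0.8, sd_auc = 0)
  expect_equal(select_operating_point(one)$n_features, 4)

  tie <- tibble::tibble(C = c(1, 1), n_features = c(50, 5),
                        mean_auc = c(0.9, 0.9), sd_auc = 0)
  expect_equal(select_operating_point(tie)$n_features, 5)

  set.seed(70)
  prof <- tibble::tibble(
    C = rep(c(1, 10, 100), each = 4),
    n_features = rep(c(2, 4, 8, 16), 3),
    mean_auc = round(runif(12, 0.5, 1), 3), sd_auc = 0)
  got <- select_operating_point(prof)
  best_by_scan <- NULL
  for (r in seq_len(nrow(prof))) {
    row <- prof[r, ]
    if (is.null(best_by_scan) ||
        row$mean_auc > best_by_scan$mean_auc ||
        (row$mean_auc == best_by_scan$mean_auc &&
         row$n_features < best_by_scan$n_features)) {
      best_by_scan <- row
    }
  }
  expect_equal(got$C, best_by_scan$C)
  expect_equal(got$n_features, best_by_scan$n_features)
})

test_that("ROC analysis matches exhaustive threshold enumeration", {
  perfect <- roc_analysis(c(1, 2, 3, 10, 11, 12), rep(c(0, 1), each = 3))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$optimal$sensitivity, 1)
  expect_equal(perfect$optimal$specificity, 1)
  expect_equal(perfect$optimal$accuracy, 1)

  flat <- roc_analysis(rep(2, 8), rep(c(0, 1), 4))
  expect_equal(flat$auc, 0.5)

  hand <- roc_analysis(c(0.1, 0.4, 0.35, 0.8, 0.7, 0.2),
                       c(0, 0, 1, 1, 1, 0))
  oh <- oracle_roc(c(0.1, 0.4, 0.35, 0.8, 0.7, 0.2), c(0, 0, 1, 1, 1, 0))
  expect_equal(hand$auc, oh$auc)
  expect_equal(hand$optimal$sensitivity, oh$optimal$sensitivity)
  expect_equal(hand$optimal$specificity, oh$optimal$specificity)
  expect_equal(hand$optimal$accuracy, oh$optimal$accuracy)

  # trapezoid AUC equals the rank-statistic formulation, ties included
  set.seed(80)
  for (rep in 1:10) {
    sc <- sample(round(runif(14, 0, 1), 1))  # coarse grid forces ties
    yy <- sample(rep(c(0, 1), 7))
    expect_equal(roc_analysis(sc, yy)$auc, oracle_roc(sc, yy)$auc,
                 tolerance = 1e-10)
  }
  expect_error(roc_analysis(1:4, rep(1, 4)), "both classes")
})

test_that("the final model selects, scales and scores consistently", {
  set.seed(90)
  n <- 30
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(n * 8), n, 8)
  X[, 3] <- y * 6 + rnorm(n, 0, 0.3)
  colnames(X) <- sprintf("f%d", 1:8)
  m <- fit_final_model(X, y, n_features = 2, C = 10, n_trees = 300,
                       rng_seed = 5)
  expect_true(3 %in% m$selected)
  tr_auc <- roc_analysis(predict_scores(m, X), y)$auc
  expect_equal(tr_auc, 1)

  # junk columns appended at prediction time are ignored
  X2 <- cbind(X, matrix(rnorm(n * 4), n, 4))
  expect_equal(predict_scores(m, X2), predict_scores(m, X))

  expect_error(fit_final_model(X, y, n_features = 99, C = 1), "exceeds")
})

test_that("region importance aggregates selected features per area", {
  info <- tibble::tibble(
    measure = rep(adspread:::MEASURE_ORDER, each = 3),
    region_label = rep(c("A01L", "A01R", "A02L"), 5))
  rk <- structure(list(order = 1:15,
                       importances = seq(0.15, 0.01, length.out = 15) /
                         sum(seq(0.15, 0.01, length.out = 15))),
                  class = "feature_ranking")

  # one feature per region
  sel <- c(1, 2, 3)
  tab <- region_importance_summary(rk, sel, info)
  expect_equal(sort(tab$importance), sort(rk$importances[1:3]))

  # all five measures of one region
  sel5 <- which(info$region_label == "A01L")
  tab5 <- region_importance_summary(rk, sel5, info)
  expect_equal(tab5$n_measures, 5)
  expect_equal(tab5$importance, sum(rk$importances[sel5]))

  # random selection equals an independent group-by sum
  set.seed(99)
  sel_r <- sample(15, 7)
  tab_r <- region_importance_summary(rk, sel_r, info)
  want <- tapply(rk$importances[sel_r], info$region_label[sel_r], sum)
  expect_equal(tab_r$importance[order(tab_r$region_label)],
               as.numeric(want[sort(names(want))]))

  # parsing from measure_region feature names
  nm <- paste(info$measure, info$region_label, sep = "_")
  tab_nm <- region_importance_summary(rk, sel5, nm)
  expect_equal(tab_nm$importance, tab5$importance)
  expect_error(region_importance_summary(rk, 1, c("nounderscore")),
               "malformed")

  prop <- measure_proportions(sel_r, info)
  expect_equal(sum(prop$percent), 100)
})
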