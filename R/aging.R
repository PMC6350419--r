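# Link-wise normal-aging model.
#
# For every connection present in all subjects of a reference cohort (the
# minimum grid mask), the streamline count is regressed on age, sex,
# age x sex and age^2 (intercept always included), with exhaustive
# best-subset selection over the 2^4 predictor subsets. The age-derivative
# of the selected model is the per-link normal-aging drift used by the
# forward simulations.

#' Minimum grid mask of a cohort
#'
#' A link belongs to the grid iff its weight is strictly positive in every
#' subject of the cohort.
#'
#' @param cohort A nonempty [cohort()].
#' @return List of class `grid_mask` with `mask` (N x N logical, symmetric,
#'   zero diagonal) and `link_list` (tibble of 0-based `i < j` indices).
#' @export
compute_grid_mask <- function(cohort) {
  if (!inherits(cohort, "cohort") || length(cohort$subjects) == 0) {
    stop("`cohort` must be a nonempty cohort", call. = FALSE)
  }
  mask <- Reduce(`&`, lapply(cohort$subjects, function(s) s$W > 0))
  diag(mask) <- FALSE
  idx <- unname(which(mask & upper.tri(mask), arr.ind = TRUE))
  structure(
    list(mask = mask,
         link_list = tibble::tibble(i = idx[, 1] - 1L, j = idx[, 2] - 1L)),
    class = "grid_mask")
}

# Predictor design for the aging regression: columns age, sex, age*sex,
# age^2, in that fixed order.
aging_design <- function(ages, sexes) {
  cbind(age = ages, sex = sexes, agesex = ages * sexes, age2 = ages^2)
}

# All 16 predictor subsets as logical rows, ordered by size then bit
# pattern so ties on the criterion resolve toward sparser models.
subset_grid <- function() {
  g <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 4)))
  colnames(g) <- c("age", "sex", "agesex", "age2")
  g[order(rowSums(g)), , drop = FALSE]
}

#' Fit link-wise aging regressions with best-subset selection
#'
#' For each grid link, all 16 subsets of the four predictors (age, sex,
#' age x sex, age^2) are fitted by ordinary least squares and the subset
#' minimizing the information criterion is kept. Coefficients of excluded
#' predictors are stored as exact zeros. A residual-sum floor makes
#' selection well-defined on noise-free data: among exact fits the sparsest
#' subset wins.
#'
#' @param cohort Fitting cohort (more than 5 subjects).
#' @param grid A [compute_grid_mask()] result.
#' @param criterion `"bic"` (default), `"aic"` or `"adjr2"`.
#' @return List of class `aging_fit` with `grid`, `models` (one tibble row
#'   per grid link: `i`, `j`, `b0`..`b4`, inclusion flags, criterion value)
#'   and `criterion`.
#' @export
fit_link_models <- function(cohort, grid, criterion = c("bic", "aic", "adjr2")) {
  criterion <- match.arg(criterion)
  n <- length(cohort$subjects)
  if (n <= 5) stop("need more than 5 subjects to fit the aging model",
                   call. = FALSE)
  X <- aging_design(cohort_ages(cohort), cohort_sexes(cohort))
  subsets <- subset_grid()
  links <- grid$link_list
  rows <- vector("list", nrow(links))
  for (l in seq_len(nrow(links))) {
    i <- links$i[l] + 1L
    j <- links$j[l] + 1L
    y <- vapply(cohort$subjects, function(s) s$W[i, j], numeric(1))
    rss_floor <- max(1e-16 * sum(y^2), 1e-24)
    tss <- sum((y - mean(y))^2)
    best <- NULL
    for (s in seq_len(nrow(subsets))) {
      inc <- subsets[s, ]
      D <- cbind(`(Intercept)` = 1, X[, inc, drop = FALSE])
      fit <- stats::lm.fit(D, y)
      if (fit$rank < ncol(D)) next  # rank-deficient candidate: skip
      rss <- max(sum(fit$residuals^2), rss_floor)
      npar <- ncol(D)
      crit <- switch(criterion,
        bic = n * log(rss / n) + npar * log(n),
        aic = n * log(rss / n) + 2 * npar,
        adjr2 = if (tss > 0) -(1 - (rss / (n - npar)) / (tss / (n - 1)))
                else n * log(rss / n) + npar * log(n))
      if (is.null(best) || crit < best$crit - 1e-12) {
        best <- list(crit = crit, inc = inc, coef = fit$coefficients)
      }
    }
    if (is.null(best)) stop(sprintf("no usable candidate model for link (%d,%d)",
                                    links$i[l], links$j[l]), call. = FALSE)
    b <- c(0, 0, 0, 0)
    b[which(best$inc)] <- best$coef[-1]
    rows[[l]] <- tibble::tibble(
      i = links$i[l], j = links$j[l],
      b0 = unname(best$coef[1]), b1 = b[1], b2 = b[2], b3 = b[3], b4 = b[4],
      inc_age = best$inc[[1]], inc_sex = best$inc[[2]],
      inc_agesex = best$inc[[3]], inc_age2 = best$inc[[4]],
      criterion_value = best$crit)
  }
  structure(list(grid = grid, models = dplyr::bind_rows(rows),
                 criterion = criterion,
                 n_regions = nrow(grid$mask)),
            class = "aging_fit")
}

#' @export
print.aging_fit <- function(x, ...) {
  cat(sprintf("<aging_fit> %d grid links, criterion %s\n",
              nrow(x$models), x$criterion))
  invisible(x)
}

#' Predicted streamline count of a fitted link model
#'
#' Evaluates the selected regression `b0 + b1 age + b2 sex + b3 age sex +
#' b4 age^2` (excluded predictors contribute 0).
#'
#' @param model One row of `aging_fit$models` (or any list with `b0`..`b4`).
#' @param age Age in years.
#' @param sex `+1` or `-1`.
#' @return Predicted weight.
#' @export
aging_prediction <- function(model, age, sex) {
  model$b0 + model$b1 * age + model$b2 * sex + model$b3 * age * sex +
    model$b4 * age^2
}

#' Normal-aging rate of a fitted link model
#'
#' The age-derivative of the link regression:
#' `b1 + b3 * sex + 2 * b4 * age` (streamlines per year).
#'
#' @inheritParams aging_prediction
#' @return Rate of weight change in streamlines per year.
#' @export
aging_rate <- function(model, age, sex) {
  model$b1 + model$b3 * sex + 2 * model$b4 * age
}

# N x N symmetric drift-coefficient matrices for one subject's sex:
# drift(t) = const + 2 * age_coef * age(t), zero off-grid.
drift_matrices <- function(fit, sex) {
  n <- fit$n_regions
  const <- matrix(0, n, n)
  age_coef <- matrix(0, n, n)
  m <- fit$models
  ii <- cbind(m$i + 1L, m$j + 1L)
  const[ii] <- m$b1 + m$b3 * sex
  age_coef[ii] <- m$b4
  const[ii[, 2:1, drop = FALSE]] <- const[ii]
  age_coef[ii[, 2:1, drop = FALSE]] <- age_coef[ii]
  list(const = const, age = age_coef)
}

# Shared snapshot -> stage_series assembly.
build_stage_series <- function(subject_id, snaps, age0, years, with_x,
                               sex = 1) {
  stages <- lapply(0:years, function(t) {
    list(stage = as.integer(years - t), t = t, age = age0 + t,
         W = snaps$W[[t + 1]],
         x = if (with_x) as.numeric(snaps$x[[t + 1]]) else NULL)
  })
  structure(list(subject_id = subject_id, sex = sex, stages = stages),
            class = "stage_series")
}

#' @export
print.stage_series <- function(x, ...) {
  cat(sprintf("<stage_series> %s: stages %d..%d\n", x$subject_id,
              x$stages[[1]]$stage, x$stages[[length(x$stages)]]$stage))
  invisible(x)
}

# Validate and convert a step size to integer steps per year.
steps_per_year_from_dt <- function(dt) {
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    stop("`dt` must be a positive number of years", call. = FALSE)
  }
  if (dt > 1) stop("`dt` must not exceed one year", call. = FALSE)
  spy <- round(1 / dt)
  if (abs(1 / dt - spy) > 1e-6) {
    stop("`dt` must divide one year (1/dt integer within rounding)",
         call. = FALSE)
  }
  as.integer(spy)
}

check_years <- function(years) {
  if (!is.numeric(years) || length(years) != 1 || years < 0 ||
      years != round(years)) {
    stop("`years` must be a non-negative integer", call. = FALSE)
  }
  as.integer(years)
}

#' Simulate normal aging of one subject
#'
#' Forward-Euler integration of the per-link aging drift on grid links only
#' (off-grid links stay constant), with weights clamped at 0 and yearly
#' snapshots recorded from the initial state onward. A `years`-year run
#' yields `years + 1` stage records, labeled `years` (baseline) down to 0.
#'
#' @param c A [connectome()] on the fit's atlas.
#' @param fit An [fit_link_models()] result.
#' @param years Non-negative integer number of years to simulate.
#' @param dt Euler step in years (default 1/52).
#' @return A `stage_series`.
#' @export
simulate_normal_aging <- function(c, fit, years = 15, dt = 1 / 52) {
  years <- check_years(years)
  spy <- steps_per_year_from_dt(dt)
  if (nrow(c$W) != fit$n_regions) {
    stop("subject and aging fit are on different atlases", call. = FALSE)
  }
  dr <- drift_matrices(fit, c$sex)
  snaps <- sim_core_cpp(c$W, numeric(nrow(c$W)), 0, 0, dr$const, dr$age,
                        c$age, years, spy, FALSE)
  build_stage_series(c$subject_id, snaps, c$age, years, with_x = FALSE,
                     sex = c$sex)
}

# A trivial aging fit with zero drift everywhere (used when simulating
# dynamics without an aging component).
null_aging_fit <- function(n_regions) {
  mask <- matrix(FALSE, n_regions, n_regions)
  structure(list(
    grid = structure(list(mask = mask,
                          link_list = tibble::tibble(i = integer(),
                                                     j = integer())),
                     class = "grid_mask"),
    models = tibble::tibble(i = integer(), j = integer(), b0 = numeric(),
                            b1 = numeric(), b2 = numeric(), b3 = numeric(),
                            b4 = numeric(), inc_age = logical(),
                            inc_sex = logical(), inc_agesex = logical(),
                            inc_age2 = logical(),
                            criterion_value = numeric()),
    criterion = "none", n_regions = n_regions), class = "aging_fit")
}
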