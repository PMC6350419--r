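# Coupled disease dynamics: weighted susceptible-infected spreading of a
# disease factor along connections, driving streamline decay, with the
# fitted normal-aging drift acting on grid links throughout.

#' Disease model parameters
#'
#' @param seed_pair Length-2 vector of 0-based region indices: the seed
#'   region and its contralateral homologue (seeding is bilateral).
#' @param alpha Infection rate per year (`>= 0`; 0 only as a null model).
#' @param beta_ad Degradation rate per year (`>= 0`).
#' @param x0 Initial infection probability of the seed regions, in (0, 1].
#' @return List of class `disease_params`.
#' @export
disease_params <- function(seed_pair, alpha, beta_ad, x0 = 0.1) {
  seed_pair <- as.integer(seed_pair)
  if (length(seed_pair) != 2 || anyNA(seed_pair) || any(seed_pair < 0)) {
    stop("`seed_pair` must be two non-negative region indices", call. = FALSE)
  }
  if (!is.numeric(alpha) || alpha < 0) stop("`alpha` must be >= 0",
                                            call. = FALSE)
  if (!is.numeric(beta_ad) || beta_ad < 0) stop("`beta_ad` must be >= 0",
                                                call. = FALSE)
  if (!is.numeric(x0) || x0 <= 0 || x0 > 1) stop("`x0` must be in (0, 1]",
                                                 call. = FALSE)
  structure(list(seed_pair = seed_pair, alpha = as.numeric(alpha),
                 beta_ad = as.numeric(beta_ad), x0 = as.numeric(x0)),
            class = "disease_params")
}

#' @export
print.disease_params <- function(x, ...) {
  cat(sprintf("<disease_params> seed (%d,%d), alpha %.3g, beta_ad %.3g, x0 %.3g\n",
              x$seed_pair[1], x$seed_pair[2], x$alpha, x$beta_ad, x$x0))
  invisible(x)
}

#' Initialize the disease state of a subject
#'
#' Infection probability `x0` on both seed regions, 0 elsewhere; the weight
#' matrix is copied from the subject.
#'
#' @param c A [connectome()].
#' @param p A [disease_params()].
#' @return List of class `disease_state` with `x`, `W`, `t`, `age`, `sex`.
#' @export
init_state <- function(c, p) {
  n <- nrow(c$W)
  if (any(p$seed_pair >= n)) {
    stop("seed index out of range for this atlas", call. = FALSE)
  }
  x <- numeric(n)
  x[p$seed_pair + 1L] <- p$x0
  structure(list(x = x, W = c$W, t = 0, age = c$age, sex = c$sex),
            class = "disease_state")
}

#' Infection rates of change
#'
#' `dx_i = alpha * (1 - x_i) * sum_{j != i} (w_ij / k_j) x_j`, with `k_j`
#' the current strength of region j; regions of zero strength contribute
#' nothing.
#'
#' @param s A `disease_state`.
#' @param p A [disease_params()].
#' @return Per-region rates (per year).
#' @export
infection_derivative <- function(s, p) {
  k <- colSums(s$W)
  xk <- ifelse(k > 0, s$x / k, 0)
  p$alpha * (1 - s$x) * as.vector(s$W %*% xk)
}

#' Connection-weight rates of change
#'
#' `dw_ij = -beta_ad * w_ij * (x_i + x_j) + drift_ij(age, sex)`, where the
#' drift is the fitted normal-aging rate on grid links and 0 off-grid.
#'
#' @param s A `disease_state`.
#' @param p A [disease_params()].
#' @param fit An `aging_fit` on the same atlas.
#' @return Symmetric matrix of rates (streamlines per year).
#' @export
weight_derivative <- function(s, p, fit) {
  dr <- drift_matrices(fit, s$sex)
  decay <- -p$beta_ad * s$W * outer(s$x, s$x, `+`)
  decay + dr$const + 2 * dr$age * s$age
}

#' One forward-Euler step of the coupled system
#'
#' Updates `x` and `W` simultaneously from the same pre-step state. `x` is
#' clamped to `[0, 1]`, weights at 0; links whose weight is exactly 0 are
#' frozen (the model never creates connections). Time and age advance by
#' `dt`.
#'
#' @param s A `disease_state`.
#' @param p A [disease_params()].
#' @param fit An `aging_fit`.
#' @param dt Step size in years (`> 0`).
#' @return The updated `disease_state`.
#' @export
step <- function(s, p, fit, dt) {
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be positive", call. = FALSE)
  dx <- infection_derivative(s, p)
  dW <- weight_derivative(s, p, fit)
  Wn <- ifelse(s$W > 0, pmax(s$W + dt * dW, 0), 0)
  s$x <- pmin(pmax(s$x + dt * dx, 0), 1)
  s$W <- Wn
  s$t <- s$t + dt
  s$age <- s$age + dt
  s
}

#' Simulate the disease course of one subject
#'
#' Integrates the coupled infection/degradation system with forward Euler
#' and records yearly snapshots, labeled stage `years` (baseline, t = 0)
#' down to stage 0 (t = `years`). A 15-year run yields 16 stages.
#'
#' @param c A [connectome()].
#' @param p A [disease_params()].
#' @param fit An `aging_fit` on the same atlas.
#' @param years Non-negative integer number of years.
#' @param dt Euler step in years, at most 1 and dividing one year.
#' @param freeze_strength If `TRUE`, region strengths `k_j` in the infection
#'   term are evaluated once on the baseline matrix instead of tracking the
#'   decaying matrix (default `FALSE`: dynamic strengths).
#' @return A `stage_series` with infection vectors at every stage.
#' @export
simulate_disease <- function(c, p, fit, years = 15, dt = 1 / 52,
                             freeze_strength = FALSE) {
  years <- check_years(years)
  spy <- steps_per_year_from_dt(dt)
  if (nrow(c$W) != fit$n_regions) {
    stop("subject and aging fit are on different atlases", call. = FALSE)
  }
  s0 <- init_state(c, p)
  dr <- drift_matrices(fit, c$sex)
  snaps <- sim_core_cpp(c$W, s0$x, p$alpha, p$beta_ad, dr$const, dr$age,
                        c$age, years, spy, freeze_strength)
  build_stage_series(c$subject_id, snaps, c$age, years, with_x = TRUE,
                     sex = c$sex)
}

#' Simulate the disease course of every subject in a cohort
#'
#' Independent per-subject simulations; each subject's own age and sex
#' drive the aging drift.
#'
#' @inheritParams simulate_disease
#' @param cohort A [cohort()] on the fit's atlas.
#' @return List of `stage_series`, one per subject, in cohort order.
#' @export
simulate_cohort <- function(cohort, p, fit, years = 15, dt = 1 / 52,
                            freeze_strength = FALSE) {
  lapply(cohort$subjects, simulate_disease, p = p, fit = fit, years = years,
         dt = dt, freeze_strength = freeze_strength)
}

#' Simulate normal aging for every subject in a cohort
#'
#' @inheritParams simulate_normal_aging
#' @param cohort A [cohort()] on the fit's atlas.
#' @return List of `stage_series`, one per subject, in cohort order.
#' @export
simulate_normal_aging_cohort <- function(cohort, fit, years = 15, dt = 1 / 52) {
  lapply(cohort$subjects, simulate_normal_aging, fit = fit, years = years,
         dt = dt)
}

#' Rebuild a cohort from one stage of simulated series
#'
#' Extracts the weight matrix at a given stage from each subject's series
#' and assembles a cohort whose metadata carries the simulated age at that
#' stage.
#'
#' @param series_list List of `stage_series` (one per subject).
#' @param region_table The shared atlas.
#' @param stage Stage index to extract (e.g. 0 for the final state).
#' @param group Group label for the rebuilt cohort.
#' @return A [cohort()].
#' @export
cohort_at_stage <- function(series_list, region_table, stage, group = "sim") {
  subjects <- lapply(series_list, function(ss) {
    rec <- NULL
    for (r in ss$stages) if (r$stage == stage) rec <- r
    if (is.null(rec)) stop(sprintf("subject %s has no stage %d", ss$subject_id,
                                   stage), call. = FALSE)
    connectome(ss$subject_id, rec$age, if (!is.null(ss$sex)) ss$sex else 1,
               group, rec$W)
  })
  cohort(region_table, subjects)
}
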