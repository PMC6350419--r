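# Inverse fitting of the disease parameters (seed region, infection rate,
# degradation rate) by exhaustive grid search: the simulated stage-0
# control-minus-patient node-strength difference is matched to a target
# difference vector in Euclidean distance.

#' Mean node-strength difference between two cohorts
#'
#' Per region, the mean node strength over `cohortA` minus the mean over
#' `cohortB`. By default strengths are computed on fraction-normalized
#' matrices so cohorts with different total streamline counts are
#' comparable; set `normalize = FALSE` for raw strengths.
#'
#' @param cohortA,cohortB Nonempty cohorts on the same atlas.
#' @param normalize Use fraction-normalized matrices (default `TRUE`).
#' @return Numeric vector of length N (A minus B).
#' @export
strength_diff_vector <- function(cohortA, cohortB, normalize = TRUE) {
  if (!identical(cohortA$region_table$label, cohortB$region_table$label)) {
    stop("cohorts must share the same region table", call. = FALSE)
  }
  if (length(cohortA$subjects) == 0 || length(cohortB$subjects) == 0) {
    stop("both cohorts must be nonempty", call. = FALSE)
  }
  mean_strength <- function(ch) {
    mats <- lapply(ch$subjects, function(s) {
      if (normalize) fraction_normalize(s$W) else s$W
    })
    Reduce(`+`, lapply(mats, strength)) / length(mats)
  }
  mean_strength(cohortA) - mean_strength(cohortB)
}

# Stage-0 mean strengths of a simulated series list (shared by
# evaluate_cost and grid_search so controls can be computed once).
stage0_mean_strength <- function(series_list, normalize = TRUE) {
  mats <- lapply(series_list, function(ss) {
    rec <- ss$stages[[length(ss$stages)]]
    stopifnot(rec$stage == 0L)
    if (normalize) fraction_normalize(rec$W) else rec$W
  })
  Reduce(`+`, lapply(mats, strength)) / length(mats)
}

#' Cost of one disease-parameter setting
#'
#' Simulates `nki_I` under normal aging and `nki_II` under the disease
#' model with parameters `p` down to stage 0, and returns the Euclidean
#' distance between the resulting control-minus-patient node-strength
#' difference vector and `target`.
#'
#' @param p A [disease_params()].
#' @param nki_I Cohort simulated as healthy controls.
#' @param nki_II Cohort simulated as patients.
#' @param fit An `aging_fit` driving the drift of both arms.
#' @param target Target difference vector of length N
#'   (controls minus patients).
#' @param years,dt Simulation horizon and Euler step.
#' @param normalize Compute strengths on fraction-normalized matrices.
#' @param controls_stage0 Optional precomputed stage-0 mean strength of the
#'   control arm (it does not depend on `p`).
#' @return Non-negative cost.
#' @export
evaluate_cost <- function(p, nki_I, nki_II, fit, target, years = 15,
                          dt = 1 / 52, normalize = TRUE,
                          controls_stage0 = NULL) {
  n <- nrow(nki_I$region_table)
  if (length(target) != n) {
    stop("`target` must have one entry per region", call. = FALSE)
  }
  if (is.null(controls_stage0)) {
    ctrl <- simulate_normal_aging_cohort(nki_I, fit, years = years, dt = dt)
    controls_stage0 <- stage0_mean_strength(ctrl, normalize)
  }
  pat <- simulate_cohort(nki_II, p, fit, years = years, dt = dt)
  diff <- controls_stage0 - stage0_mean_strength(pat, normalize)
  sqrt(sum((diff - target)^2))
}

#' Exhaustive grid search over (seed pair, alpha, beta_ad)
#'
#' Evaluates [evaluate_cost()] at every combination of candidate seed pair,
#' infection rate and degradation rate, returning the full cost surface and
#' the deterministic argmin (first minimum in enumeration order: seeds in
#' the given order, then `alpha`, then `beta_ad`).
#'
#' @param nki_I,nki_II Cohorts for the control and patient simulation arms.
#' @param fit An `aging_fit`.
#' @param target Target difference vector (controls minus patients).
#' @param seed_candidates 2-column matrix of 0-based (region, homologue)
#'   pairs, or `NULL` for every bilateral pair of the atlas.
#' @param alpha_grid,beta_grid Parameter grids (defaults 0.1..1.0 by 0.1
#'   and 0.005..0.05 by 0.005).
#' @param years,dt Simulation horizon and Euler step.
#' @param x0 Initial seed infection probability used for every candidate.
#' @param normalize Compute strengths on fraction-normalized matrices.
#' @return List of class `fit_result` with `best_params`, `best_cost` and
#'   `surface` (tibble: `seed_i`, `seed_j`, `seed_label`, `alpha`,
#'   `beta_ad`, `cost`).
#' @export
grid_search <- function(nki_I, nki_II, fit, target, seed_candidates = NULL,
                        alpha_grid = seq(0.1, 1, by = 0.1),
                        beta_grid = seq(0.005, 0.05, by = 0.005),
                        years = 15, dt = 1 / 52, x0 = 0.1, normalize = TRUE) {
  if (length(alpha_grid) == 0 || length(beta_grid) == 0) {
    stop("parameter grids must be nonempty", call. = FALSE)
  }
  rt <- nki_I$region_table
  if (is.null(seed_candidates)) seed_candidates <- atlas_seed_pairs(rt)
  seed_candidates <- matrix(as.integer(seed_candidates), ncol = 2)
  if (nrow(seed_candidates) == 0) stop("no seed candidates", call. = FALSE)
  ctrl <- simulate_normal_aging_cohort(nki_I, fit, years = years, dt = dt)
  controls_stage0 <- stage0_mean_strength(ctrl, normalize)
  rows <- vector("list", nrow(seed_candidates) * length(alpha_grid) *
                   length(beta_grid))
  r <- 0L
  best <- NULL
  for (s in seq_len(nrow(seed_candidates))) {
    sp <- seed_candidates[s, ]
    for (a in alpha_grid) {
      for (b in beta_grid) {
        p <- disease_params(sp, a, b, x0 = x0)
        cost <- evaluate_cost(p, nki_I, nki_II, fit, target, years = years,
                              dt = dt, normalize = normalize,
                              controls_stage0 = controls_stage0)
        r <- r + 1L
        rows[[r]] <- tibble::tibble(seed_i = sp[1], seed_j = sp[2],
                                    seed_label = rt$label[sp[1] + 1L],
                                    alpha = a, beta_ad = b, cost = cost)
        if (is.null(best) || cost < best$cost) {
          best <- list(params = p, cost = cost)
        }
      }
    }
  }
  structure(list(best_params = best$params, best_cost = best$cost,
                 surface = dplyr::bind_rows(rows)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  p <- x$best_params
  cat(sprintf("<fit_result> seed (%d,%d), alpha %.3g, beta_ad %.3g, cost %.4g (%d grid points)\n",
              p$seed_pair[1], p$seed_pair[2], p$alpha, p$beta_ad,
              x$best_cost, nrow(x$surface)))
  invisible(x)
}

#' Per-seed minimum cost profile
#'
#' Collapses a grid-search surface to the minimum cost attained by each
#' candidate seed pair over the (alpha, beta_ad) grid.
#'
#' @param fit_result A [grid_search()] result.
#' @return Tibble with `seed_i`, `seed_j`, `seed_label`, `min_cost`, sorted
#'   ascending.
#' @export
seed_cost_profile <- function(fit_result) {
  fit_result$surface |>
    dplyr::group_by(seed_i, seed_j, seed_label) |>
    dplyr::summarise(min_cost = min(cost), .groups = "drop") |>
    dplyr::arrange(min_cost)
}
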