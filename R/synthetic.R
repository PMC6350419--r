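# Synthetic connectome cohorts with known ground truth.
#
# The generator emulates the statistical structure the analysis assumes:
# every subject shares a core set of connections (default 126 on an
# 82-region atlas) whose weights follow the link-wise age/sex regression
# with known coefficients plus truncated Gaussian noise, plus a few random
# subject-specific off-core links. Patient cohorts are produced by running
# the disease model itself with known parameters, so inverse fitting has a
# well-posed ground truth.

#' Generator configuration
#'
#' @param n_region_pairs Bilateral pairs in the atlas (default 41, N = 82).
#' @param n_core_links Connections shared by all subjects (default 126).
#' @param n_extra_links_per_subject Random off-core links per subject.
#' @param noise_sd Standard deviation of additive weight noise (streamlines).
#' @param weight_scale Typical streamline-count scale of core links.
#' @param rng_seed Seed fixing every random draw of the generator.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_region_pairs = 41, n_core_links = 126,
                             n_extra_links_per_subject = 30, noise_sd = 2,
                             weight_scale = 100, rng_seed = 1) {
  n <- 2L * as.integer(n_region_pairs)
  max_links <- n * (n - 1) / 2
  if (n_core_links > max_links) {
    stop("`n_core_links` exceeds the number of unique region pairs",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(list(n_region_pairs = as.integer(n_region_pairs),
                 n_core_links = as.integer(n_core_links),
                 n_extra_links_per_subject = as.integer(n_extra_links_per_subject),
                 noise_sd = as.numeric(noise_sd),
                 weight_scale = as.numeric(weight_scale),
                 rng_seed = as.integer(rng_seed)),
            class = "generator_config")
}

# Sample `m` unique undirected links on `n` nodes. When m >= n - 1 a random
# spanning tree is embedded first so the core graph is connected (the
# spreading dynamics and path-based centralities assume a connected core).
sample_core_links <- function(n, m) {
  links <- NULL
  if (m >= n - 1) {
    perm <- sample.int(n) - 1L
    tree <- cbind(perm[1:(n - 1)], perm[2:n])
    tree <- t(apply(tree, 1, sort))
    links <- tree
  }
  key <- function(l) l[, 1] * n + l[, 2]
  used <- if (is.null(links)) integer() else key(links)
  while (is.null(links) || nrow(links) < m) {
    need <- m - if (is.null(links)) 0L else nrow(links)
    a <- sample.int(n, 2 * need, replace = TRUE) - 1L
    b <- sample.int(n, 2 * need, replace = TRUE) - 1L
    cand <- cbind(pmin(a, b), pmax(a, b))
    cand <- cand[cand[, 1] != cand[, 2], , drop = FALSE]
    cand <- cand[!duplicated(key(cand)) & !(key(cand) %in% used), ,
                 drop = FALSE]
    if (nrow(cand) == 0) next
    take <- utils::head(cand, need)
    links <- rbind(links, take)
    used <- c(used, key(take))
  }
  links[order(key(links)), , drop = FALSE]
}

# Draw ground-truth regression coefficients for each core link. Intercepts
# are positive and O(weight_scale); the age/sex effects are small relative
# to the intercept with random signs, and each of the four predictors is
# independently included with probability 1/2 (intercept always in).
# Intercepts are raised where needed so the noise-free weight stays above
# `margin` over ages 45-81 and both sexes, guaranteeing the core survives
# the minimum grid mask.
draw_true_coefficients <- function(links, scale, margin) {
  m <- nrow(links)
  rsign <- function(k) sample(c(-1, 1), k, replace = TRUE)
  inc <- matrix(stats::runif(4 * m) < 0.5, m, 4)
  colnames(inc) <- c("age", "sex", "agesex", "age2")
  b0 <- stats::runif(m, 0.5, 2) * scale
  b1 <- ifelse(inc[, 1], rsign(m) * stats::runif(m, 0.001, 0.004) * scale, 0)
  b2 <- ifelse(inc[, 2], rsign(m) * stats::runif(m, 0.02, 0.08) * scale, 0)
  b3 <- ifelse(inc[, 3], rsign(m) * stats::runif(m, 0.0005, 0.002) * scale, 0)
  b4 <- ifelse(inc[, 4], rsign(m) * stats::runif(m, 2e-5, 6e-5) * scale, 0)
  ages <- seq(45, 96, by = 0.5)  # cover the fitted range plus 15 aging years
  for (l in seq_len(m)) {
    vals <- outer(ages, c(-1, 1), function(a, s) {
      b0[l] + b1[l] * a + b2[l] * s + b3[l] * a * s + b4[l] * a^2
    })
    deficit <- margin - min(vals)
    if (deficit > 0) b0[l] <- b0[l] + deficit
  }
  tibble::tibble(i = links[, 1], j = links[, 2], b0 = b0, b1 = b1, b2 = b2,
                 b3 = b3, b4 = b4, inc_age = inc[, 1], inc_sex = inc[, 2],
                 inc_agesex = inc[, 3], inc_age2 = inc[, 4])
}

eval_truth <- function(truth, age, sex) {
  truth$b0 + truth$b1 * age + truth$b2 * sex + truth$b3 * age * sex +
    truth$b4 * age^2
}

# One subject's weight matrix from ground-truth coefficients.
sample_subject_W <- function(n, truth, age, sex, noise_sd, n_extra, scale) {
  W <- matrix(0, n, n)
  mu <- eval_truth(truth, age, sex)
  if (any(mu <= 0)) {
    l <- which(mu <= 0)[1]
    stop(sprintf("configuration makes core link (%d,%d) non-positive (mean %.3g)",
                 truth$i[l], truth$j[l], mu[l]), call. = FALSE)
  }
  w <- pmax(mu + stats::rnorm(length(mu), 0, noise_sd), 0)
  W[cbind(truth$i + 1L, truth$j + 1L)] <- w
  if (n_extra > 0) {
    core_key <- truth$i * n + truth$j
    got <- 0L
    while (got < n_extra) {
      a <- sample.int(n, 1) - 1L
      b <- sample.int(n, 1) - 1L
      if (a == b) next
      ij <- c(min(a, b), max(a, b))
      if ((ij[1] * n + ij[2]) %in% core_key || W[ij[1] + 1, ij[2] + 1] > 0) next
      W[ij[1] + 1, ij[2] + 1] <- stats::runif(1, scale / 20, scale / 2)
      got <- got + 1L
    }
  }
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  W
}

#' Generate a healthy-adult cohort with known aging ground truth
#'
#' Produces a cohort of 52 adults (26 of each sex, ages uniform on 45-81)
#' whose core-link weights follow the link-wise age/sex regression with
#' known coefficients plus truncated Gaussian noise, over a connected core
#' of `n_core_links` connections shared by all subjects; each subject also
#' gets random subject-specific off-core links. Equal seeds give identical
#' cohorts.
#'
#' @param config A [generator_config()].
#' @param n_subjects Number of subjects (even; default 52).
#' @return List with `cohort` and `truth`; `truth` holds the per-link
#'   coefficients with inclusion masks and the core link list.
#' @export
generate_nki_like_cohort <- function(config = generator_config(),
                                     n_subjects = 52) {
  n <- 2L * config$n_region_pairs
  rt <- generate_atlas(config$n_region_pairs)
  with_rng(config$rng_seed, {
    links <- sample_core_links(n, config$n_core_links)
    margin <- max(8 * config$noise_sd, 0.02 * config$weight_scale)
    truth <- draw_true_coefficients(links, config$weight_scale, margin)
    ages <- stats::runif(n_subjects, 45, 81)
    sexes <- rep(c(1, -1), length.out = n_subjects)
    subjects <- lapply(seq_len(n_subjects), function(k) {
      W <- sample_subject_W(n, truth, ages[k], sexes[k], config$noise_sd,
                            config$n_extra_links_per_subject,
                            config$weight_scale)
      connectome(sprintf("nki%03d", k), ages[k], sexes[k], "healthy", W)
    })
    list(cohort = cohort(rt, subjects),
         truth = list(true_link_coefficients = truth,
                      core_link_list = tibble::tibble(i = links[, 1],
                                                      j = links[, 2]),
                      true_disease_params = NULL))
  })
}

#' Convert generator ground truth into an aging fit
#'
#' Wraps the true link coefficients as an `aging_fit` so simulations can be
#' driven by the exact generative drift instead of an estimated one.
#'
#' @param truth Ground-truth list from [generate_nki_like_cohort()].
#' @param n_regions Atlas dimension.
#' @return An `aging_fit`.
#' @export
truth_as_aging_fit <- function(truth, n_regions) {
  tc <- truth$true_link_coefficients
  mask <- matrix(FALSE, n_regions, n_regions)
  mask[cbind(tc$i + 1L, tc$j + 1L)] <- TRUE
  mask <- mask | t(mask)
  structure(list(
    grid = structure(list(mask = mask,
                          link_list = tibble::tibble(i = tc$i, j = tc$j)),
                     class = "grid_mask"),
    models = dplyr::mutate(tc, criterion_value = NA_real_),
    criterion = "truth", n_regions = n_regions), class = "aging_fit")
}

#' Generate matched control/patient cohorts via the disease model
#'
#' Builds `n_pairs` baseline subjects (ages centered near `74 - years` so
#' the evolved cohorts are around age 74; 20 male / 19 female at the
#' default size), then evolves each baseline twice: under normal aging only
#' (control k) and under the disease model with `disease_params`
#' (patient k). Patient k therefore shares control k's baseline — a
#' counterfactual twin — making the pair exactly age- and sex-matched and
#' the disease parameters a recoverable ground truth.
#'
#' @param config A [generator_config()] (atlas and weight structure).
#' @param disease_params A [disease_params()] used to create patients.
#' @param aging_fit An `aging_fit` driving the drift (e.g.
#'   [truth_as_aging_fit()] or [fit_link_models()]).
#' @param years Simulated years between baseline and the observed state.
#' @param n_pairs Number of matched control/patient pairs (default 39).
#' @param dt Euler step for the simulations.
#' @return List with `controls`, `patients` (cohorts) and `truth`
#'   (records `disease_params`).
#' @export
generate_adni_like_cohorts <- function(config, disease_params, aging_fit,
                                       years = 15, n_pairs = 39, dt = 1 / 52) {
  n <- 2L * config$n_region_pairs
  if (aging_fit$n_regions != n) {
    stop("aging fit and generator config are on different atlases",
         call. = FALSE)
  }
  if (any(disease_params$seed_pair >= n)) {
    stop("seed index out of range for this atlas", call. = FALSE)
  }
  rt <- generate_atlas(config$n_region_pairs)
  gen <- with_rng(config$rng_seed + 1L, {
    truth <- aging_fit$models
    ages0 <- pmin(pmax(stats::rnorm(n_pairs, 74 - years, 5), 55), 88 - years)
    n_m <- ceiling(n_pairs * 20 / 39)
    sexes <- c(rep(1, n_m), rep(-1, n_pairs - n_m))
    baselines <- lapply(seq_len(n_pairs), function(k) {
      W <- sample_subject_W(n, truth, ages0[k], sexes[k], config$noise_sd,
                            config$n_extra_links_per_subject,
                            config$weight_scale)
      connectome(sprintf("adni%03d", k), ages0[k], sexes[k], "baseline", W)
    })
    baselines
  })
  controls <- lapply(gen, function(b) {
    ss <- simulate_normal_aging(b, aging_fit, years = years, dt = dt)
    rec <- ss$stages[[length(ss$stages)]]
    connectome(paste0(b$subject_id, "c"), rec$age, b$sex, "control", rec$W)
  })
  patients <- lapply(gen, function(b) {
    ss <- simulate_disease(b, disease_params, aging_fit, years = years,
                           dt = dt)
    rec <- ss$stages[[length(ss$stages)]]
    connectome(paste0(b$subject_id, "p"), rec$age, b$sex, "patient", rec$W)
  })
  list(controls = cohort(rt, controls),
       patients = cohort(rt, patients),
       truth = list(true_disease_params = disease_params))
}

#' Split a cohort into two age- and sex-matched halves
#'
#' Subjects are sorted within sex by age and alternately assigned, giving
#' two halves with closely matched age and sex composition (used to form
#' the simulated control and to-be-patient groups).
#'
#' @param cohort A [cohort()] with an even number of subjects.
#' @return List with cohorts `groupI` and `groupII`.
#' @export
split_matched_groups <- function(cohort) {
  ages <- cohort_ages(cohort)
  sexes <- cohort_sexes(cohort)
  ord <- order(sexes, ages)
  gI <- ord[seq(1, length(ord), by = 2)]
  gII <- ord[seq(2, length(ord), by = 2)]
  list(groupI = cohort_subset(cohort, sort(gI)),
       groupII = cohort_subset(cohort, sort(gII)))
}
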