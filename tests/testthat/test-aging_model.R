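test_that("grid mask keeps exactly the links shared by all subjects", {
  rt <- generate_atlas(2)
  base <- matrix(0, 4, 4)
  W1 <- base; W1[1, 2] <- W1[2, 1] <- 1; W1[2, 3] <- W1[3, 2] <- 2
  W2 <- W1; W2[1, 4] <- W2[4, 1] <- 5
  W3 <- W1
  ch <- cohort(rt, list(toy_connectome(W1, "a"), toy_connectome(W2, "b"),
                        toy_connectome(W3, "c")))
  gm <- compute_grid_mask(ch)
  expect_equal(nrow(gm$link_list), 2)
  expect_equal(gm$link_list$i, c(0L, 1L))
  expect_equal(gm$link_list$j, c(1L, 2L))

  # one zero weight excludes the link for everyone
  W3z <- W3; W3z[1, 2] <- W3z[2, 1] <- 0
  chz <- cohort(rt, list(toy_connectome(W1, "a"), toy_connectome(W2, "b"),
                         toy_connectome(W3z, "c")))
  expect_equal(compute_grid_mask(chz)$link_list$i, 1L)
  expect_error(compute_grid_mask(cohort(rt, list())), "nonempty")
})

test_that("noise-free best-subset fits recover the ground truth exactly", {
  gen <- generate_nki_like_cohort(
    generator_config(noise_sd = 0, n_extra_links_per_subject = 0,
                     rng_seed = 31))
  fit <- fit_link_models(gen$cohort, compute_grid_mask(gen$cohort))
  m <- dplyr::inner_join(fit$models, gen$truth$true_link_coefficients,
                         by = c("i", "j"), suffix = c("", ".t"))
  expect_equal(nrow(m), 126)
  expect_identical(m$inc_age, m$inc_age.t)
  expect_identical(m$inc_sex, m$inc_sex.t)
  expect_identical(m$inc_agesex, m$inc_agesex.t)
  expect_identical(m$inc_age2, m$inc_age2.t)
  for (b in c("b0", "b1", "b2", "b3", "b4")) {
    expect_equal(m[[b]], m[[paste0(b, ".t")]], tolerance = 1e-8)
  }
  # and the fitted surface reproduces every core weight
  for (s in gen$cohort$subjects[c(3, 40)]) {
    pred <- aging_prediction(fit$models, s$age, s$sex)
    expect_equal(s$W[cbind(fit$models$i + 1L, fit$models$j + 1L)], pred,
                 tolerance = 1e-8)
  }
})

test_that("a constant link selects the intercept-only model", {
  rt <- generate_atlas(2)
  subs <- lapply(1:10, function(k) {
    W <- matrix(0, 4, 4)
    W[1, 2] <- W[2, 1] <- 7  # constant across subjects
    W[3, 4] <- W[4, 3] <- 1 + 0.5 * (40 + k)  # age-dependent
    toy_connectome(W, paste0("s", k), age = 40 + k,
                   sex = if (k %% 2) 1 else -1)
  })
  ch <- cohort(rt, subs)
  fit <- fit_link_models(ch, compute_grid_mask(ch))
  const_row <- fit$models[fit$models$i == 0, ]
  expect_false(any(const_row$inc_age, const_row$inc_sex,
                   const_row$inc_agesex, const_row$inc_age2))
  expect_equal(const_row$b0, 7)
  age_row <- fit$models[fit$models$i == 2, ]
  expect_true(age_row$inc_age)
  expect_equal(age_row$b1, 0.5, tolerance = 1e-8)
})

test_that("coefficient error shrinks as generator noise shrinks", {
  rmse <- vapply(c(0.5, 0.1, 0.01), function(ns) {
    gen <- generate_nki_like_cohort(
      generator_config(noise_sd = ns, n_extra_links_per_subject = 0,
                       rng_seed = 77))
    fit <- fit_link_models(gen$cohort, compute_grid_mask(gen$cohort))
    m <- dplyr::inner_join(fit$models, gen$truth$true_link_coefficients,
                           by = c("i", "j"), suffix = c("", ".t"))
    sqrt(mean((m$b0 - m$b0.t)^2 + (m$b1 - m$b1.t)^2 + (m$b2 - m$b2.t)^2 +
                (m$b3 - m$b3.t)^2 + (m$b4 - m$b4.t)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})

test_that("aging_rate is the exact age-derivative of the link model", {
  m0 <- list(b0 = 5, b1 = 0, b2 = 0, b3 = 0, b4 = 0)
  expect_equal(aging_rate(m0, 60, 1), 0)
  m <- list(b0 = 2, b1 = 1, b2 = 0.3, b3 = 0.5, b4 = 0.1)
  expect_equal(aging_rate(m, 50, 1), 11.5)
  # centered finite difference oracle
  set.seed(2)
  for (k in 1:5) {
    mk <- list(b0 = runif(1, 0, 10), b1 = runif(1, -1, 1),
               b2 = runif(1, -1, 1), b3 = runif(1, -1, 1),
               b4 = runif(1, -0.05, 0.05))
    age <- runif(1, 45, 81)
    sex <- sample(c(-1, 1), 1)
    h <- 1e-4
    fd <- (aging_prediction(mk, age + h, sex) -
             aging_prediction(mk, age - h, sex)) / (2 * h)
    expect_equal(aging_rate(mk, age, sex), fd, tolerance = 1e-6)
  }
})

test_that("normal-aging simulation integrates the drift correctly", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 10
  W[3, 4] <- W[4, 3] <- 20
  c0 <- toy_connectome(W, "t", age = 60, sex = 1)

  # zero rates: nothing moves
  fit0 <- manual_aging_fit(4, list(c(0, 1, 10, 0, 0, 0, 0)))
  ss0 <- simulate_normal_aging(c0, fit0, years = 15, dt = 1 / 52)
  expect_length(ss0$stages, 16)
  expect_identical(ss0$stages[[16]]$W, W)
  expect_equal(ss0$stages[[16]]$stage, 0L)
  expect_equal(ss0$stages[[1]]$stage, 15L)

  # constant rate: Euler is exact, off-grid links untouched
  fitc <- manual_aging_fit(4, list(c(0, 1, 0, 0.5, 0, 0, 0)))
  ssc <- simulate_normal_aging(c0, fitc, years = 15, dt = 1 / 52)
  expect_equal(ssc$stages[[16]]$W[1, 2], 10 + 0.5 * 15, tolerance = 1e-9)
  expect_equal(ssc$stages[[16]]$W[3, 4], 20)

  # quadratic-age drift follows the closed-form regression trajectory
  b <- c(b0 = 120, b1 = -0.9, b2 = 4, b3 = 0.1, b4 = -0.004)
  w0 <- b["b0"] + b["b1"] * 60 + b["b2"] + b["b3"] * 60 + b["b4"] * 60^2
  Wq <- matrix(0, 4, 4)
  Wq[1, 2] <- Wq[2, 1] <- w0
  cq <- toy_connectome(Wq, "q", age = 60, sex = 1)
  fitq <- manual_aging_fit(4, list(c(0, 1, b)))
  ssq <- simulate_normal_aging(cq, fitq, years = 15, dt = 1 / 365)
  w15 <- b["b0"] + b["b1"] * 75 + b["b2"] + b["b3"] * 75 + b["b4"] * 75^2
  expect_lt(abs(ssq$stages[[16]]$W[1, 2] - w15) / w15, 0.001)

  # clamping: strongly negative drift cannot push a weight below zero
  fitn <- manual_aging_fit(4, list(c(0, 1, 0, -5, 0, 0, 0)))
  ssn <- simulate_normal_aging(c0, fitn, years = 15, dt = 1 / 52)
  expect_equal(ssn$stages[[16]]$W[1, 2], 0)
  expect_true(all(ssn$stages[[16]]$W >= 0))
  expect_identical(ssn$stages[[16]]$W, t(ssn$stages[[16]]$W))

  expect_error(simulate_normal_aging(c0, fit0, years = -1), "non-negative")
  expect_error(simulate_normal_aging(c0, fit0, years = 5, dt = 0), "positive")
})

test_that("stronger true effects are selected at least as often", {
  rt <- generate_atlas(2)
  freq_for <- function(b1) {
    hits <- 0L
    for (seed in 1:20) {
      set.seed(seed)
      ages <- runif(14, 45, 81)
      sexes <- rep(c(1, -1), 7)
      subs <- lapply(seq_along(ages), function(k) {
        W <- matrix(0, 4, 4)
        W[1, 2] <- W[2, 1] <- 100 + b1 * ages[k] + rnorm(1, 0, 3)
        toy_connectome(W, paste0("s", k), age = ages[k], sex = sexes[k])
      })
      ch <- cohort(rt, subs)
      fit <- fit_link_models(ch, compute_grid_mask(ch))
      hits <- hits + fit$models$inc_age[1]
    }
    hits / 20
  }
  freqs <- vapply(c(0.02, 0.3, 1.5), freq_for, numeric(1))
  expect_true(all(diff(freqs) >= 0))
  expect_gt(freqs[3], freqs[1])
})
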