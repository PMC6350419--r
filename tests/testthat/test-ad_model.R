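test_that("disease state initialization seeds both homologues only", {
  W <- sym(matrix(1, 4, 4))
  c0 <- toy_connectome(W, "t")
  s <- init_state(c0, disease_params(c(0, 1), 0.4, 0.02, x0 = 1))
  expect_equal(s$x, c(1, 1, 0, 0))
  expect_equal(s$t, 0)
  s2 <- init_state(c0, disease_params(c(0, 1), 0.4, 0.02, x0 = 1))
  expect_identical(s, s2)
  expect_error(init_state(c0, disease_params(c(0, 9), 0.4, 0.02)),
               "out of range")
  expect_error(disease_params(c(0, 1), 0.4, 0.02, x0 = 0), "x0")
  expect_error(disease_params(c(0, 1), -1, 0.02), "alpha")
})

test_that("infection derivative follows the weighted SI law", {
  W <- sym(matrix(c(0, 2, 1, 0, 0, 3, 0, 0, 0), 3, 3, byrow = TRUE))
  c0 <- toy_connectome(W, "t")
  p <- disease_params(c(0, 1), 0.7, 0)
  s <- init_state(c0, p)
  s$x <- c(0.2, 0.5, 0.9)

  # saturated state is a fixed point
  s1 <- s; s1$x <- rep(1, 3)
  expect_equal(infection_derivative(s1, p), rep(0, 3))

  # linear in the infection rate
  p2 <- disease_params(c(0, 1), 1.4, 0)
  expect_equal(infection_derivative(s, p2), 2 * infection_derivative(s, p))

  # independent scalar-loop evaluation
  k <- colSums(W)
  want <- numeric(3)
  for (i in 1:3) {
    acc <- 0
    for (j in 1:3) if (j != i && k[j] > 0) acc <- acc + W[i, j] / k[j] * s$x[j]
    want[i] <- 0.7 * (1 - s$x[i]) * acc
  }
  expect_equal(infection_derivative(s, p), want)
})

test_that("weight derivative couples decay to nodal infection burden", {
  W <- sym(matrix(2, 4, 4))
  c0 <- toy_connectome(W, "t", age = 70, sex = -1)
  fit <- manual_aging_fit(4, list(c(0, 1, 5, 0.3, 0, 0.1, 0.002),
                                  c(2, 3, 5, -0.2, 0, 0, 0)))
  p <- disease_params(c(0, 1), 0.4, 0.05)
  s <- init_state(c0, p)

  # no infection anywhere: pure aging drift
  s0 <- s; s0$x <- rep(0, 4)
  dW <- weight_derivative(s0, p, fit)
  expect_equal(dW[1, 2], aging_rate(list(b1 = 0.3, b3 = 0.1, b4 = 0.002),
                                    70, -1))
  expect_equal(dW[3, 4], -0.2)
  expect_equal(dW[1, 3], 0)  # off-grid: no drift
  expect_identical(dW, t(dW))

  # beta_ad = 0 ignores x entirely
  pb0 <- disease_params(c(0, 1), 0.4, 0)
  s$x <- c(1, 0.5, 0, 0)
  expect_equal(weight_derivative(s, pb0, fit),
               weight_derivative(s0, pb0, fit))

  # full infection with no drift: exponential decay at rate 2*beta_ad
  W2 <- matrix(c(0, 8, 8, 0), 2, 2)
  st <- list(x = c(1, 1), W = W2, t = 0, age = 70, sex = 1)
  class(st) <- "disease_state"
  pfull <- disease_params(c(0, 1), 0, 0.025)
  nullf <- null_fit(2)
  dt <- 1 / 365
  for (k in seq_len(15 * 365)) st <- step(st, pfull, nullf, dt)
  expect_lt(abs(st$W[1, 2] - 8 * exp(-2 * 0.025 * 15)) /
              (8 * exp(-2 * 0.025 * 15)), 0.001)
})

test_that("euler steps preserve invariants and reduce to closed forms", {
  W <- sym(matrix(1.5, 4, 4))
  c0 <- toy_connectome(W, "t")
  nullf <- null_fit(4)
  p0 <- disease_params(c(0, 1), 0, 0, x0 = 0.3)
  s <- init_state(c0, p0)
  s1 <- step(s, p0, nullf, 0.5)
  expect_identical(s1$W, s$W)
  expect_identical(s1$x, s$x)
  expect_equal(s1$t, 0.5)

  # infection probabilities never decrease
  p <- disease_params(c(0, 1), 0.8, 0.03)
  s <- init_state(c0, p)
  for (k in 1:100) {
    s2 <- step(s, p, nullf, 1 / 52)
    expect_true(all(s2$x >= s$x - 1e-15))
    expect_true(all(s2$x <= 1))
    s <- s2
  }

  # two symmetric nodes follow the logistic growth curve
  W2 <- matrix(c(0, 5, 5, 0), 2, 2)
  c2 <- toy_connectome(W2, "two")
  pl <- disease_params(c(0, 1), 0.4, 0, x0 = 0.1)
  ss <- simulate_disease(c2, pl, null_fit(2), years = 10, dt = 1 / 1000)
  xT <- ss$stages[[11]]$x[1]
  closed <- 0.1 * exp(0.4 * 10) / (1 + 0.1 * (exp(0.4 * 10) - 1))
  expect_lt(abs(xT - closed), 1e-3)
})

test_that("disease simulation stages and convergence behave as specified", {
  gen <- small_cohort(seed = 13)
  n <- nrow(gen$cohort$region_table)
  fit <- truth_as_aging_fit(gen$truth, n)
  c0 <- gen$cohort$subjects[[1]]
  p <- disease_params(c(0, 1), 0.4, 0.025)

  ss <- simulate_disease(c0, p, fit, years = 15, dt = 1 / 52)
  expect_length(ss$stages, 16)
  expect_equal(vapply(ss$stages, `[[`, integer(1), "stage"), 15:0)

  ss0 <- simulate_disease(c0, p, fit, years = 0, dt = 1 / 52)
  expect_length(ss0$stages, 1)
  expect_equal(ss0$stages[[1]]$stage, 0L)
  expect_identical(ss0$stages[[1]]$W, c0$W)

  # dt refinement changes stage-0 strengths by well under 0.5%
  sA <- simulate_disease(c0, p, fit, years = 15, dt = 1 / 52)
  sB <- simulate_disease(c0, p, fit, years = 15, dt = 1 / 104)
  kA <- strength(sA$stages[[16]]$W)
  kB <- strength(sB$stages[[16]]$W)
  expect_lt(max(abs(kA - kB) / pmax(kB, 1e-12)), 0.005)

  expect_error(simulate_disease(c0, p, fit, years = 15, dt = 2), "one year")
})

test_that("simulated patients match per-subject runs and subject order", {
  gen <- small_cohort(seed = 17, n_subjects = 4)
  n <- nrow(gen$cohort$region_table)
  fit <- truth_as_aging_fit(gen$truth, n)
  p <- disease_params(c(2, 3), 0.5, 0.02)
  one <- cohort_subset(gen$cohort, 2)
  expect_identical(simulate_cohort(one, p, fit, years = 5, dt = 1 / 12)[[1]],
                   simulate_disease(gen$cohort$subjects[[2]], p, fit,
                                    years = 5, dt = 1 / 12))
  perm <- c(3, 1, 4, 2)
  sims <- simulate_cohort(gen$cohort, p, fit, years = 5, dt = 1 / 12)
  sims_p <- simulate_cohort(cohort_subset(gen$cohort, perm), p, fit,
                            years = 5, dt = 1 / 12)
  expect_identical(sims_p[[2]], sims[[1]])

  # null disease reproduces normal aging exactly
  pnull <- disease_params(c(0, 1), 0, 0)
  a <- simulate_cohort(gen$cohort, pnull, fit, years = 5, dt = 1 / 12)
  b <- lapply(gen$cohort$subjects, simulate_normal_aging, fit = fit,
              years = 5, dt = 1 / 12)
  for (k in seq_along(a)) {
    for (st in seq_along(a[[k]]$stages)) {
      expect_identical(a[[k]]$stages[[st]]$W, b[[k]]$stages[[st]]$W)
    }
  }
})

test_that("support is conserved and infection reaches the whole network", {
  # a zero link stays zero even under positive drift pressure
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 3
  c0 <- toy_connectome(W, "z")
  fit <- manual_aging_fit(4, list(c(0, 1, 1, 0.2, 0, 0, 0),
                                  c(2, 3, 1, 0.9, 0, 0, 0)))
  ss <- simulate_normal_aging(c0, fit, years = 10, dt = 1 / 12)
  expect_equal(ss$stages[[11]]$W[3, 4], 0)

  # alpha * t = 20 saturates every connected node
  set.seed(33)
  for (rep in 1:3) {
    Wc <- rand_connected_W(8)
    cc <- toy_connectome(Wc, "c")
    p <- disease_params(c(0, 1), 2, 0, x0 = 0.1)
    ss <- simulate_disease(cc, p, null_fit(8), years = 10, dt = 1 / 52)
    expect_gt(min(ss$stages[[11]]$x), 0.5)
  }
})

test_that("R-level stepping and the compiled core agree", {
  gen <- small_cohort(seed = 19)
  n <- nrow(gen$cohort$region_table)
  fit <- truth_as_aging_fit(gen$truth, n)
  c0 <- gen$cohort$subjects[[2]]
  p <- disease_params(c(0, 1), 0.5, 0.03)
  ss <- simulate_disease(c0, p, fit, years = 2, dt = 1 / 52)
  st <- init_state(c0, p)
  for (k in 1:104) st <- step(st, p, fit, 1 / 52)
  expect_equal(st$W, ss$stages[[3]]$W, tolerance = 1e-12)
  expect_equal(st$x, ss$stages[[3]]$x, tolerance = 1e-12)
})
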