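test_that("parameter validation and the noise-free limit hold", {
  expect_error(ou_params(-1, 0, 1), "theta")
  expect_error(ou_params(1, 0, 0), "beta_inv")
  p <- ou_params(0.3, 2, 1e-12, x0 = 8)
  sim <- simulate_ou(p, 0:20, 3, seed = 1)
  expected <- 2 + (8 - 2) * exp(-0.3 * (0:20))
  for (i in 1:3) expect_equal(sim$states[i, ], expected, tolerance = 1e-4)
})

test_that("stationary variance and autocorrelation match closed forms", {
  theta <- 0.5
  beta_inv <- 2
  p <- ou_params(theta, 5, beta_inv, x0 = 5)
  sim <- simulate_ou(p, seq(0, 40, by = 1), 2000, seed = 2)
  # start at mu: mean stays mu, variance relaxes to beta_inv / theta
  expect_lt(abs(mean(sim$states[, 41]) - 5), 3 * sqrt(4 / 2000))
  v <- var(sim$states[, 41])
  se_v <- 4 * sqrt(2 / 1999)
  expect_lt(abs(v - beta_inv / theta), 3 * se_v)
  # lag-Delta autocorrelation at stationarity
  lag <- 2
  rho <- cor(sim$states[, 35], sim$states[, 35 + lag])
  expect_lt(abs(rho - exp(-theta * lag)), 3 * (1 - exp(-theta * lag)^2) / sqrt(2000))
})

test_that("log-likelihood matches hand-computed Gaussian densities", {
  p <- ou_params(0.4, 1, 0.8)
  x <- c(2, 1.5)
  dt <- 3
  e <- exp(-0.4 * dt)
  m <- 1 + (2 - 1) * e
  v <- 0.8 / 0.4 * (1 - e^2)
  expect_equal(
    ou_loglik(p, c(0, dt), x),
    dnorm(1.5, m, sqrt(v), log = TRUE)
  )
  # unconditioned version adds the stationary density of the first point
  expect_equal(
    ou_loglik(p, c(0, dt), x, condition_first = FALSE),
    dnorm(1.5, m, sqrt(v), log = TRUE) + dnorm(2, 1, sqrt(2), log = TRUE)
  )
  # at a huge gap the transition density approaches the stationary one
  expect_equal(
    ou_loglik(p, c(0, 1e6), x),
    dnorm(1.5, 1, sqrt(2), log = TRUE),
    tolerance = 1e-9
  )
  expect_error(ou_loglik(p, c(0, 0), x), "duplicate")
})

test_that("likelihood is maximized near the generating parameters", {
  p <- ou_params(1, 5, 1, x0 = 3)
  sim <- simulate_ou(p, seq(0, 200, by = 0.5), 1, seed = 3)
  ll_true <- ou_loglik(p, sim$times, sim$states[1, ])
  for (pert in list(
    ou_params(2, 5, 1), ou_params(0.5, 5, 1),
    ou_params(1, 7, 1), ou_params(1, 5, 2.5)
  )) {
    expect_gt(ll_true, ou_loglik(pert, sim$times, sim$states[1, ]))
  }
})

test_that("joint MLE recovers parameters from a simulated cohort", {
  set.seed(4)
  true <- ou_params(1, 5, 1)
  paths <- lapply(1:20, function(i) {
    x0 <- rnorm(1, 5, 1)
    sim <- simulate_ou(
      ou_params(1, 5, 1, x0 = x0),
      seq(0, 12, by = 1), 1,
      seed = 400 + i
    )
    data.frame(
      patient_id = sprintf("p%02d", i), time = sim$times,
      state = sim$states[1, ], group = "FP"
    )
  })
  traj <- do.call(rbind, paths)
  class(traj) <- c("trajectory_set", "data.frame")
  fit <- fit_ou(traj)$FP
  expect_true(fit$converged)
  expect_lt(abs(fit$params$theta - 1) / 1, 0.35)
  expect_lt(abs(fit$params$mu - 5) / 5, 0.2)
  expect_lt(abs(fit$params$beta_inv - 1) / 1, 0.35)
})

test_that("bridge backcasts honor endpoints and analytic moments", {
  p <- ou_params(0.4, 3, 1.5)
  b <- backcast(p, x_at_zero = 2, t_back_months = 30, n_paths = 3000,
    seed = 5, n_steps = 30
  )
  expect_equal(b$states[, ncol(b$states)], rep(2, 3000))
  expect_equal(b$states[, 1], rep(0, 3000))
  expect_equal(range(b$times), c(-30, 0))

  # oracle: condition unconstrained forward simulations on the endpoint
  grid <- seq(-30, 0, by = 1)
  free <- simulate_ou(ou_params(0.4, 3, 1.5, x0 = 0), grid, 60000, seed = 6)
  endpoint <- free$states[, length(grid)]
  sel <- abs(endpoint - 2) < 0.08
  mid <- which(grid == -15)
  cond_mean <- mean(free$states[sel, mid])
  cond_sd <- sd(free$states[sel, mid])
  bmid <- which.min(abs(b$times - (-15)))
  expect_lt(abs(mean(b$states[, bmid]) - cond_mean),
    3 * cond_sd / sqrt(sum(sel)) + 3 * cond_sd / sqrt(3000)
  )
  expect_lt(abs(sd(b$states[, bmid]) - cond_sd), 0.15 * cond_sd)

  # vanishing noise collapses the bridge onto a deterministic curve
  b0 <- backcast(ou_params(0.4, 3, 1e-10), 2, 30, 5, seed = 7)
  expect_lt(max(apply(b0$states, 2, sd)), 1e-4)
})

test_that("forward backcast mode ignores the endpoint", {
  p <- ou_params(0.4, 3, 1.5)
  f <- backcast(p, 2, 30, 500, seed = 8, mode = "forward")
  expect_equal(f$states[, 1], rep(0, 500))
  expect_gt(sd(f$states[, ncol(f$states)]), 0.5)
})

test_that("downsampling restricts paths without re-simulation", {
  p <- ou_params(0.5, 0, 1, x0 = 0)
  sim <- simulate_ou(p, 0:20, 50, seed = 9)
  full <- downsample_paths(sim, 0:20)
  expect_equal(full$states, sim$states)
  sub <- downsample_paths(sim, c(0, 6, 13, 20))
  expect_equal(sub$states, sim$states[, c(1, 7, 14, 21)])
  interp <- downsample_paths(sim, c(0, 5.5))
  expect_equal(
    interp$states[, 2],
    (sim$states[, 6] + sim$states[, 7]) / 2
  )
  expect_error(downsample_paths(sim, c(-1, 5)), "outside")
})

test_that("PC1 separates planted groups with the FP-high orientation", {
  co <- tiny_cohort(seed = 91, n_proteins = 100, n_signal = 30, effect = 3)
  tr <- pc1_trajectories(co$matrix, co$metadata)
  expect_gt(
    mean(tr$state[tr$group == "FP"]),
    mean(tr$state[tr$group == "SP"])
  )
  # permuting protein order leaves projections unchanged
  perm <- sample(nrow(co$matrix$values))
  shuffled <- abundance_matrix(co$matrix$values[perm, ], scale = "log2")
  tr2 <- pc1_trajectories(shuffled, co$metadata)
  expect_equal(tr$state, tr2$state, tolerance = 1e-9)
})

test_that("FP proteome variance exceeds SP across generator seeds", {
  # medians over 5-6 patients are noisy; require a clear majority of
  # seeds above 1 plus a solidly elevated median ratio
  ratios <- vapply(1:12, function(s) {
    co <- generate_cohort(cohort_spec(
      n_proteins = 500, within_patient_sd_fast = 0.9,
      within_patient_sd_slow = 0.3, seed = 100 + s
    ))
    variance_biomarker(pc1_trajectories(co$matrix, co$metadata))$ratio
  }, 0)
  expect_gte(sum(ratios > 1), 9)
  expect_gt(median(ratios), 1.5)
})

test_that("symmetric generators give a variance ratio near one", {
  set.seed(92)
  ratios <- vapply(1:8, function(s) {
    co <- generate_cohort(cohort_spec(
      n_fast = 8, n_slow = 8, n_proteins = 200,
      within_patient_sd_fast = 0.5, within_patient_sd_slow = 0.5,
      n_signal_proteins = 0, seed = 200 + s
    ))
    variance_biomarker(pc1_trajectories(co$matrix, co$metadata))$ratio
  }, 0)
  expect_lt(abs(median(log(ratios))), log(2))
  # single-visit patients are excluded with a warning
  tr <- trajectory_set(
    c("a", "a", "b"), c(0, 3, 0), c(1, 2, 5), c("FP", "FP", "SP")
  )
  expect_warning(variance_biomarker(tr), "single-visit")
})
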