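test_that("the velocity update is the stated Euler-Maruyama step", {
  expect_equal(step_velocity(1, 100, 0, 0.1, 0), 0.999)
  expect_equal(step_velocity(2, 50, 1.5, 0.5, 1),
               2 * (1 - 0.01) + sqrt(2 * 1.5^2 * 0.5 / 50))
  expect_error(step_velocity(1, 0.05, 1, 0.1, 0), "unstable")
})

test_that("the Langevin chain has the stationary variance and exponential autocorrelation", {
  set.seed(101)
  tau <- 10; dt <- 0.25; sigma <- 1.5
  n_w <- 4000; n_s <- 1200
  v <- matrix(NA_real_, n_w, n_s)
  v[, 1] <- rnorm(n_w, 0, sigma)
  for (i in 2:n_s)
    v[, i] <- step_velocity(v[, i - 1], tau, sigma, dt, rnorm(n_w))
  # stationary variance sigma^2 (1 + O(dt/tau)) within Monte-Carlo error
  vall <- as.numeric(v[, -(1:100)])
  expect_lt(abs(var(vall) - sigma^2), 0.06 * sigma^2)
  # lag-k autocorrelation ~ exp(-k dt / tau) out to ~3 tau
  for (k in c(4, 16, 40, 120)) {
    ac <- mean(v[, 200] * v[, 200 + k]) / sigma^2
    se <- sd(v[, 200] * v[, 200 + k]) / sigma^2 / sqrt(n_w)
    expect_lt(abs(ac - exp(-k * dt / tau)), 3 * se)
  }
})

test_that("simulated phases are zero-mean with the predicted variance", {
  w <- make_dde(strength_for_b(100, DELTA, DDELTA), DELTA, DDELTA, 50)
  e <- simulate_phases(w, tau = 200, sigma_v = 1.5, n_walkers = 20000,
                       dt = 0.1, seed = 31)
  phi <- e$phases[, 1]
  expect_lt(abs(mean(phi)), 3 * sd(phi) / sqrt(length(phi)))
  phi2_pred <- phase_variance_numeric(w, vacf("exponential", 3 * 1.5^2, 200))
  se_var <- sd(phi^2) / sqrt(length(phi))
  expect_lt(abs(var(phi) - phi2_pred), 3 * se_var)
})

test_that("phases collapse to a delta-like distribution for FC in the ballistic regime", {
  w <- make_dde(strength_for_b(200, DELTA, DDELTA), DELTA, DDELTA, 50,
                flow_compensated = TRUE)
  e <- simulate_phases(w, tau = 2e6, sigma_v = 1.5, n_walkers = 4000,
                       dt = 0.1, seed = 32)
  expect_lt(sd(e$phases[, 1]), 0.01)
  expect_lt(max(abs(e$phases[, 1])), 0.05)
})

test_that("phase distributions match the zero-mean Gaussian with the predicted variance", {
  G <- strength_for_b(100, DELTA, DDELTA)
  w <- make_dde(G, DELTA, DDELTA, 50)
  for (tau in c(5, 50, 5000)) {      # T/tau = 10, 1, 0.01 at T = 50 ms
    e <- simulate_phases(w, tau, 1.5, n_walkers = 20000, dt = 0.1,
                         seed = 33)
    phi2 <- phase_variance_numeric(w, vacf("exponential", 3 * 1.5^2, tau))
    ks <- ks.test(e$phases[, 1], "pnorm", 0, sqrt(phi2))
    expect_gt(ks$p.value, 0.01)
    # Shapiro-Wilk on a subsample corroborates normality per se
    sub <- e$phases[seq(1, 20000, length.out = 4000), 1]
    expect_gt(shapiro.test(sub)$p.value, 0.001)
  }
})

test_that("ensemble signal matches its analytic expectation and is seed-deterministic", {
  # all-zero phases give F_P = 1
  e0 <- structure(list(phases = matrix(0, 500, 1), labels = "null",
                       n_walkers = 500), class = "walker_ensemble")
  s0 <- ensemble_signal(e0)
  expect_equal(s0$fp, 1)
  expect_equal(s0$fp_cos, 1)
  # Gaussian phases: E F_P = exp(-s^2/2) (Gaussian characteristic function)
  set.seed(44)
  s <- 1.3
  eg <- structure(list(phases = matrix(rnorm(40000, 0, s), 40000, 1),
                       labels = "gauss", n_walkers = 40000),
                  class = "walker_ensemble")
  sg <- ensemble_signal(eg)
  expect_lt(abs(sg$fp_cos - exp(-s^2 / 2)), 3 * sg$se_cos)
  expect_lt(abs(sg$fp - exp(-s^2 / 2)), 4 * sg$se)
  # identical seeds reproduce the ensemble bitwise
  w <- make_dde(40, DELTA, DDELTA, 50)
  e1 <- simulate_phases(w, 130, 1.5, n_walkers = 1000, seed = 9)
  e2 <- simulate_phases(w, 130, 1.5, n_walkers = 1000, seed = 9)
  expect_identical(e1$phases, e2$phases)
})

test_that("simulated ensemble attenuation reproduces the closed form for FC and NC", {
  sigma <- 1.5; tau <- 200; T <- 50
  bs <- c(10, 30, 100)
  ws <- c(lapply(bs, function(b) make_dde(strength_for_b(b, DELTA, DDELTA),
                                          DELTA, DDELTA, T)),
          lapply(bs, function(b) make_dde(strength_for_b(b, DELTA, DDELTA),
                                          DELTA, DDELTA, T, TRUE)))
  e <- simulate_phases(ws, tau, sigma, n_walkers = 20000, dt = 0.1,
                       seed = 13)
  s <- ensemble_signal(e)
  p <- ivim_params(f = 1, D = 0, v = sqrt(3) * sigma, tau = tau)
  ana <- fp_closed_form(p, strength_for_b(rep(bs, 2), DELTA, DDELTA),
                        DELTA, DDELTA, T, rep(c(1, -1), each = 3))
  expect_true(all(abs(s$fp_cos - ana) < 3 * s$se_cos))
  # FC recovers at least as much signal as NC (within Monte-Carlo error)
  expect_true(all(s$fp[4:6] >= s$fp[1:3] - 3 * pmax(s$se[1:3], s$se[4:6])))
})

test_that("halving the time step changes the ensemble signal by less than one SE", {
  w <- make_dde(strength_for_b(100, DELTA, DDELTA), DELTA, DDELTA, 50)
  s1 <- ensemble_signal(simulate_phases(w, 130, 1.5, 20000, dt = 0.1,
                                        seed = 17))
  s2 <- ensemble_signal(simulate_phases(w, 130, 1.5, 20000, dt = 0.05,
                                        seed = 17))
  expect_lt(abs(s1$fp_cos - s2$fp_cos), max(s1$se_cos, s2$se_cos))
  # too-coarse steps are refined with a warning
  expect_warning(simulate_phases(w, tau = 1, sigma_v = 1.5, n_walkers = 10,
                                 dt = 0.5, seed = 1), "refined")
})
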