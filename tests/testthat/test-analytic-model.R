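test_that("Psi and Omega match their compact product forms and limits", {
  taus <- c(5, 20, 130, 500, 1000)
  for (tau in taus) {
    psi_prod <- 2 * exp(-(DDELTA + DELTA) / tau) * (exp(DELTA / tau) - 1) *
      (2 * exp(DDELTA / tau) + exp(DELTA / tau) - 1)
    expect_lt(rel_err(psi_dde(tau, DELTA, DDELTA), psi_prod), 1e-12)
    for (m in c(1, -1)) {
      om_prod <- m * (exp(DDELTA / tau) - 1)^2 * (exp(DELTA / tau) - 1)^2 *
        exp(-50 / tau)
      expect_lt(rel_err(omega_dde(tau, DELTA, DDELTA, 50, m), om_prod),
                1e-10)
    }
  }
  # m-antisymmetry holds exactly
  expect_equal(omega_dde(130, DELTA, DDELTA, 60, 1),
               -omega_dde(130, DELTA, DDELTA, 60, -1))
  # Omega is suppressed exponentially with the encoding time
  expect_lt(abs(omega_dde(50, DELTA, DDELTA, 1000, 1)), 1e-8)
  # Psi stays bounded as tau -> 0 so tau^3 Psi vanishes (diffusive reduction)
  expect_lt(1e-6^3 * psi_dde(1e-6, DELTA, DDELTA), 1e-15)
  # smoothness scan: finite over three decades of tau
  expect_true(all(is.finite(psi_dde(exp(seq(log(1), log(1000),
                                            length.out = 200)),
                                    DELTA, DDELTA))))
  expect_error(omega_dde(100, DELTA, DDELTA, 60, 2), "m must be")
  expect_error(psi_dde(-1, DELTA, DDELTA), "tau")
})

test_that("closed-form attenuation agrees with the quadrature oracle on a parameter grid", {
  v2 <- 6.75
  grid <- expand.grid(tau = c(5, 20, 60, 200, 800),
                      delta = c(4, 8.6), Delta = c(10, 14),
                      T = c(50, 100), m = c(1, -1))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- ivim_params(f = 1, D = 0, v = sqrt(v2), tau = g$tau)
    w <- make_dde(40, g$delta, g$Delta, g$T, flow_compensated = g$m < 0)
    phi2 <- phase_variance_numeric(w, vacf("exponential", v2, g$tau))
    expect_lt(rel_err(fp_closed_form(p, 40, g$delta, g$Delta, g$T, g$m),
                      exp(-phi2 / 2)), 1e-6)
  }
})

test_that("attenuation is 1 without flow and decreases with gradient strength for NC", {
  p0 <- ivim_params(f = 0.05, D = 0.9, v = 0, tau = 130)
  expect_equal(fp_closed_form(p0, 40, DELTA, DDELTA, 50, 1), 1)
  expect_equal(fp_closed_form(p0, 40, DELTA, DDELTA, 50, -1), 1)
  p <- brain_params()
  G <- seq(0, 60, by = 5)
  fp <- fp_closed_form(p, G, DELTA, DDELTA, 50, 1)
  expect_true(all(diff(fp) <= 0))
  expect_equal(fp[1], 1)
  expect_true(all(fp > 0 & fp <= 1))
})

test_that("flow compensation can only rephase: F_P(FC) >= F_P(NC)", {
  set.seed(5)
  for (k in 1:25) {
    p <- ivim_params(f = 1, D = 0, v = runif(1, 0.3, 4),
                     tau = exp(runif(1, log(1), log(1000))))
    T <- runif(1, 37.3, 120)
    G <- runif(1, 5, 60)
    expect_gte(fp_closed_form(p, G, DELTA, DDELTA, T, -1),
               fp_closed_form(p, G, DELTA, DDELTA, T, 1) - 1e-14)
  }
  # FC and NC coincide once the pair coupling has decayed (T >> tau)
  p <- ivim_params(f = 1, D = 0, v = 1.5, tau = 4)
  expect_lt(rel_err(fp_closed_form(p, 40, DELTA, DDELTA, 100, -1),
                    fp_closed_form(p, 40, DELTA, DDELTA, 100, 1)), 1e-8)
})

test_that("the closed form approaches the pseudodiffusive limit as tau -> 0", {
  # the diffusive reduction needs tau small against the lobe timing itself:
  # the -4 delta tau^2 bracket term is ~80 % of the diffusive term at
  # tau = 5 ms with delta = 8.6 ms, and falls below 1 % only near tau ~ 0.9 ms
  # (in-protocol b-grid, b up to 200 s/mm^2)
  bs <- c(5, 10, 20, 30, 100, 200)
  G <- strength_for_b(bs, DELTA, DDELTA)
  p <- ivim_params(f = 1, D = 0, v = sqrt(3) * 1.5, tau = 0.5)
  err <- rel_err(fp_closed_form(p, G, DELTA, DDELTA, 100, 1),
                 fp_diffusive(p, bs))
  expect_lt(max(err), 0.01)
  # and the agreement tightens as tau decreases further
  p2 <- ivim_params(f = 1, D = 0, v = sqrt(3) * 1.5, tau = 0.1)
  err2 <- rel_err(fp_closed_form(p2, G, DELTA, DDELTA, 100, 1),
                  fp_diffusive(p2, bs))
  expect_lt(max(err2), max(err))
  expect_equal(fp_diffusive(p, 0), 1)
  expect_equal(fp_diffusive(ivim_params(1, 0, 0, 10), 200), 1)
})

test_that("the closed form approaches the ballistic limit as tau -> Inf", {
  bs <- c(5, 10, 20, 30, 100, 200)
  G <- strength_for_b(bs, DELTA, DDELTA)
  p <- ivim_params(f = 1, D = 0, v = sqrt(3) * 1.5, tau = 1e6)
  w <- lapply(bs, function(b) make_dde(strength_for_b(b, DELTA, DDELTA),
                                       DELTA, DDELTA, 50))
  cs <- vapply(w, cvalue, 0)
  err_nc <- rel_err(fp_closed_form(p, G, DELTA, DDELTA, 50, 1),
                    fp_ballistic(p, cs, 1))
  expect_lt(max(err_nc), 0.005)
  # FC is fully rephased in the ballistic regime
  expect_true(all(abs(fp_closed_form(p, G, DELTA, DDELTA, 50, -1) - 1)
                  < 0.005))
  expect_equal(fp_ballistic(p, cs, -1), rep(1, length(cs)))
  expect_equal(fp_ballistic(ivim_params(1, 0, 0, 10), 0.5, 1), 1)
})

test_that("the FC attenuation is non-monotonic in tau with an interior minimum", {
  ratios <- exp(seq(log(0.5), log(15), length.out = 120))   # T/tau
  p_of <- function(tau) ivim_params(f = 1, D = 0, v = sqrt(3) * 1.5,
                                    tau = tau)
  G <- strength_for_b(100, DELTA, DDELTA)
  fp <- vapply(ratios, function(r)
    fp_closed_form(p_of(50 / r), G, DELTA, DDELTA, 50, -1), 0)
  i_min <- which.min(fp)
  expect_gt(i_min, 1)
  expect_lt(i_min, length(ratios))
  expect_gte(ratios[i_min], 3)
  expect_lte(ratios[i_min], 6)
})

test_that("the two-compartment signal has the correct algebraic structure", {
  pro <- default_protocol()
  p <- brain_params()
  s <- ivim_signal(p, pro)
  expect_equal(s[pro$b == 0], rep(1, sum(pro$b == 0)))
  # f = 0: monoexponential tissue decay, FC and NC identical
  p0 <- ivim_params(f = 0, D = 0.91, v = 1.51, tau = 130)
  s0 <- ivim_signal(p0, pro)
  expect_equal(s0, exp(-pro$b * 0.91e-3), tolerance = 1e-12)
  # f = 1 in a deeply diffusive regime: exp(-b (D* + Db))
  pd <- ivim_params(f = 1, D = 0.5, v = sqrt(3) * 1.5, tau = 0.05)
  sd1 <- ivim_signal(pd, pro)
  Dstar <- (1.5e-3 * sqrt(3))^2 * 0.05e-3 / 3 * 1e9   # um^2/ms
  expect_equal(sd1, exp(-pro$b * (Dstar + 1.75) * 1e-3), tolerance = 1e-3)
  # regime descriptor
  expect_identical(flow_regime(10, 100), "diffusive")
  expect_identical(flow_regime(130, 100), "intermediate")
  expect_identical(flow_regime(800, 100), "ballistic")
})
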