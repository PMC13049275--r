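test_that("the log posterior enforces the priors and recomputes deterministically", {
  pro <- quick_protocol()
  p <- brain_params()
  dat <- as.numeric(noisefree_dataset(p, pro))
  truth <- c(D = 0.91, f = 0.0475, v = 1.51, tau = 130, S0 = 1)
  # outside any prior bound the density is -Inf
  for (bad in list(c(D = -0.1), c(D = 3.5), c(f = 1.2), c(v = 5.5),
                   c(tau = 0.5), c(tau = 1500), c(S0 = -1))) {
    th <- truth; th[names(bad)] <- bad
    expect_identical(log_posterior(th, dat, pro), -Inf)
  }
  # the generating parameters beat perturbed ones on noise-free data
  lp_true <- log_posterior(truth, dat, pro, noise_sd = 0.01)
  for (shift in list(c(D = 0.2), c(f = 0.03), c(v = -0.5), c(tau = 200),
                     c(S0 = 0.05))) {
    th <- truth; th[names(shift)] <- th[names(shift)] + shift
    expect_gt(lp_true, log_posterior(th, dat, pro, noise_sd = 0.01))
  }
  # density matches a direct recomputation of the marginalized form
  th2 <- c(D = 1.2, f = 0.1, v = 2, tau = 80, S0 = 0.98)
  pp <- ivim_params(th2[["f"]], th2[["D"]], th2[["v"]], th2[["tau"]],
                    th2[["S0"]])
  rss <- sum((dat - ivim_signal(pp, pro))^2)
  expect_lt(abs(log_posterior(th2, dat, pro) -
                (-(length(dat) / 2) * log(rss))), 1e-12)
  expect_error(log_posterior(truth, dat[-1], pro), "match")
})

test_that("noise-free data recover the generating parameters", {
  pro <- default_protocol()
  p <- brain_params()
  dat <- noisefree_dataset(p, pro)
  fit <- suppressWarnings(fit_voxel(dat, pro, n_samples = 6000,
                                    burn_in = 3000, seed = 21,
                                    noise_sd = 1e-4))
  est <- coef(fit)
  expect_lt(rel_err(est[["D"]], 0.91), 0.02)
  expect_lt(rel_err(est[["f"]], 0.0475), 0.02)
  expect_lt(rel_err(est[["S0"]], 1), 0.02)
  expect_lt(rel_err(est[["v"]], 1.51), 0.05)
  expect_lt(rel_err(est[["tau"]], 130), 0.05)
  expect_true(all(fit$summary$rhat < 1.2, na.rm = TRUE))
})

test_that("the posterior concentrates around truth as the likelihood tightens", {
  pro <- quick_protocol()
  dat <- noisefree_dataset(brain_params(), pro)
  widths <- vapply(c(3e-3, 5e-4, 1e-4), function(sig) {
    fit <- suppressWarnings(fit_voxel(dat, pro, n_samples = 3000,
                                      burn_in = 2000, seed = 22,
                                      noise_sd = sig))
    s <- fit$summary
    s$q97.5[s$parameter == "v"] - s$q2.5[s$parameter == "v"]
  }, 0)
  expect_true(all(diff(widths) < 0))
})

test_that("every posterior draw respects the prior box", {
  pro <- quick_protocol()
  p <- brain_params()
  dat <- add_rician(noisefree_dataset(p, pro), snr = 40, seed = 3)
  fit <- suppressWarnings(fit_voxel(dat, pro, n_samples = 3000,
                                    burn_in = 1500, seed = 23,
                                    keep_chain = TRUE))
  ch <- fit$chain
  expect_true(all(ch[, "D"] >= 0 & ch[, "D"] <= 3))
  expect_true(all(ch[, "f"] >= 0 & ch[, "f"] <= 1))
  expect_true(all(ch[, "v"] >= 0 & ch[, "v"] <= 5))
  expect_true(all(ch[, "tau"] >= 1 & ch[, "tau"] <= 1000))
  expect_true(all(ch[, "S0"] >= 0 & ch[, "S0"] <= 2 * max(dat)))
  # medians lie inside the prior bounds too
  expect_true(all(fit$summary$median >= c(0, 0, 0, 1, 0)))
})

test_that("degenerate or unidentifiable inputs are rejected", {
  pro <- quick_protocol()
  dat <- as.numeric(noisefree_dataset(brain_params(), pro))
  expect_error(fit_voxel(rep(0, nrow(pro)), pro), "degenerate")
  expect_error(fit_voxel(c(NA, dat[-1]), pro), "degenerate")
  one_T <- default_protocol(b = c(0, 5, 100, 200), T_ms = c(50, 60))
  one_T <- one_T[one_T$T == 50, ]
  expect_error(fit_voxel(dat[seq_len(nrow(one_T))], one_T),
               "encoding times")
})

test_that("fit_map handles masks and reduces to fit_voxel per voxel", {
  pro <- quick_protocol()
  p <- brain_params()
  vox <- synthetic_voxels(p, pro, snr = 60, n_voxels = 3, seed = 41)
  mask <- c(TRUE, FALSE, TRUE)
  maps <- fit_map(vox, pro, mask = mask, seed = 7, n_samples = 1200,
                  burn_in = 600)
  expect_true(all(is.na(maps$median[2, ])))
  expect_false(anyNA(maps$median[c(1, 3), ]))
  direct <- suppressWarnings(fit_voxel(vox[1, ], pro, seed = 7 + 1,
                                       n_samples = 1200, burn_in = 600))
  expect_equal(unname(maps$median[1, ]), unname(coef(direct)))
  # 4-D array input produces one small map per parameter
  vol <- aperm(array(vox[1:2, ], c(2, nrow(pro), 1, 1)), c(1, 3, 4, 2))
  maps4 <- fit_map(vol, pro, seed = 7, n_samples = 800, burn_in = 400)
  expect_named(maps4$median, c("D", "f", "v", "tau", "S0"))
  expect_equal(dim(maps4$median$f), c(2, 1, 1))
  expect_error(fit_map(vox[, -1], pro), "match")
})

test_that("bootstrap CI of the median is reproducible, degenerate-safe and calibrated", {
  expect_error(bootstrap_median_ci(1), "two values")
  cst <- bootstrap_median_ci(rep(2.5, 30), n_boot = 500, seed = 1)
  expect_equal(unname(cst$ci), c(2.5, 2.5))
  set.seed(10)
  x <- rnorm(400)
  b1 <- bootstrap_median_ci(x, n_boot = 2000, seed = 2)
  b2 <- bootstrap_median_ci(x, n_boot = 2000, seed = 2)
  expect_identical(b1$ci, b2$ci)
  # roughly symmetric about the median for a symmetric sample
  expect_lt(abs((b1$ci[2] - b1$median) - (b1$median - b1$ci[1])), 0.15)
  # coverage of the true median near the nominal level
  set.seed(11)
  n_rep <- 400
  cover <- vapply(seq_len(n_rep), function(i) {
    ci <- bootstrap_median_ci(rnorm(60), n_boot = 1500, seed = 1000 + i)$ci
    ci[1] <= 0 && 0 <= ci[2]
  }, TRUE)
  p_hat <- mean(cover)
  se <- sqrt(0.95 * 0.05 / n_rep)
  expect_lt(abs(p_hat - 0.95), 3 * se + 0.02)
})
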