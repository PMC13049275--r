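# Voxel-wise Bayesian estimation of (D, f, v, tau, S0) from FC/NC multi-T
# magnitude data under the closed-form DDE model, with random-walk
# Metropolis sampling (componentwise, with adaptive proposal scales during
# burn-in). The blood diffusivity Db is fixed.

.PRIOR_BOUNDS <- list(D = c(0, 3),      # um^2/ms
                      f = c(0, 1),
                      v = c(0, 5),      # mm/s
                      tau = c(1, 1000)) # ms; S0 in [0, 2 max(signal)]

# precomputed per-protocol constants (SI where needed)
.protocol_const <- function(protocol, delta = attr(protocol, "delta"),
                            Delta = attr(protocol, "Delta"), Db = 1.75,
                            d = 3) {
  if (is.null(delta) || is.null(Delta))
    .stopf("protocol must carry delta and Delta")
  G <- strength_for_b(protocol$b, delta, Delta)
  g2G2 <- (GAMMA_1H * .mTm(G))^2
  key <- paste(protocol$T, protocol$m)
  uk <- !duplicated(key)
  list(n = nrow(protocol),
       b = protocol$b,
       bD_fac = protocol$b * 1e-3,          # multiply by D in um^2/ms
       blood = exp(-protocol$b * 1e-3 * Db),
       g2G2 = g2G2,
       x_s = .ms(delta), y_s = .ms(Delta),
       T_u = .ms(protocol$T)[uk], m_u = protocol$m[uk],
       u_index = match(key, key[uk]),
       d = d, Db = Db)
}

# phi2 / v^2 (v in mm/s): the tau-dependent coefficient vector
.phi2_coef <- function(const, tau_ms) {
  tau_s <- .ms(tau_ms)
  x <- const$x_s / tau_s
  y <- const$y_s / tau_s
  br <- .psi_tilde(x, y) +
    .omega_tilde(x, y, const$T_u / tau_s, const$m_u)[const$u_index]
  2 * const$g2G2 * (1e-6 / const$d) * tau_s^4 * br
}

.model_signal_const <- function(const, D, f, v, tau, S0) {
  fp <- exp(-.phi2_coef(const, tau) * v^2 / 2)
  S0 * ((1 - f) * exp(-const$bD_fac * D) + f * fp * const$blood)
}

#' Log-posterior of the FC/NC multi-T IVIM model
#'
#' Uniform priors D in [0, 3] um^2/ms, f in [0, 1], v in [0, 5] mm/s,
#' tau in [1, 1000] ms and S0 in [0, 2 max(data)] (log-density `-Inf`
#' outside), with a Gaussian likelihood on the magnitude signals. When
#' `noise_sd` is `NULL` the noise SD is marginalized analytically under a
#' Jeffreys prior, giving `loglik = -(n/2) log(RSS)` up to a constant;
#' otherwise the fixed-sigma Gaussian log-likelihood is used. The blood
#' diffusivity is fixed at `Db`.
#'
#' @param theta Named numeric vector with elements `D`, `f`, `v`, `tau`,
#'   `S0`.
#' @param data Measured signal vector, aligned with `protocol` rows.
#' @param protocol Protocol data frame with columns `b`, `T`, `m` and
#'   timing attributes (see [default_protocol()]).
#' @param noise_sd Optional fixed noise SD.
#' @param Db Fixed blood diffusivity, um^2/ms.
#' @return Log posterior density (up to an additive constant).
#' @export
log_posterior <- function(theta, data, protocol, noise_sd = NULL,
                          Db = 1.75) {
  if (length(data) != nrow(protocol))
    .stopf("data length (%d) does not match protocol rows (%d)",
           length(data), nrow(protocol))
  th <- as.list(theta[c("D", "f", "v", "tau", "S0")])
  bounds <- c(.PRIOR_BOUNDS, list(S0 = c(0, 2 * max(data))))
  for (nm in names(bounds)) {
    val <- th[[nm]]
    if (is.na(val) || val < bounds[[nm]][1] || val > bounds[[nm]][2])
      return(-Inf)
  }
  const <- .protocol_const(protocol, Db = Db)
  sig <- .model_signal_const(const, th$D, th$f, th$v, th$tau, th$S0)
  rss <- sum((data - sig)^2)
  if (is.null(noise_sd)) {
    -(const$n / 2) * log(rss)
  } else {
    -rss / (2 * noise_sd^2) - const$n * log(noise_sd)
  }
}

# crude data-driven starting point, clamped inside the prior box
.init_theta <- function(data, protocol) {
  S0 <- mean(data[protocol$b == 0])
  if (!is.finite(S0) || S0 <= 0) S0 <- max(data)
  hb <- protocol$b >= 100 & protocol$m == 1
  D <- if (sum(hb) >= 2) {
    fit <- stats::lm(log(pmax(data[hb], 1e-12)) ~ I(protocol$b[hb] * 1e-3))
    -unname(stats::coef(fit)[2])
  } else 1
  D <- min(max(D, 0.2), 2.8)
  f0 <- 1 - exp(stats::lm(log(pmax(data[hb], 1e-12)) ~
                            I(protocol$b[hb] * 1e-3))$coefficients[1]) / S0
  f <- min(max(unname(f0), 0.01), 0.3)
  c(D = D, f = f, v = 2.5, tau = sqrt(1 * 1000), S0 = S0)
}

.split_rhat <- function(x, n_split = 4) {
  n <- floor(length(x) / n_split)
  if (n < 2) return(NA_real_)
  chunks <- matrix(x[seq_len(n * n_split)], n, n_split)
  W <- mean(apply(chunks, 2, stats::var))
  B_over_n <- stats::var(colMeans(chunks))
  if (W <= 0) return(1)
  sqrt((n - 1) / n + B_over_n / W)
}

#' Fit the IVIM model to one voxel by MCMC
#'
#' Componentwise random-walk Metropolis on (D, f, v, log tau, S0) (the
#' correlation-time prior spans three decades, so tau is proposed on the
#' log scale with the Jacobian keeping its prior uniform). Proposal scales
#' adapt towards a 44 % acceptance rate during burn-in and are frozen
#' afterwards; proposals outside the prior bounds are rejected.
#'
#' @param data Signal vector aligned with `protocol` (at least 10 points
#'   spanning at least two encoding times and both FC and NC — otherwise
#'   tau and v are not separable).
#' @param protocol Protocol data frame.
#' @param n_samples Retained posterior draws (after burn-in).
#' @param burn_in Burn-in iterations (discarded).
#' @param seed RNG seed.
#' @param noise_sd Optional fixed noise SD; `NULL` marginalizes it (see
#'   [log_posterior()]).
#' @param Db Fixed blood diffusivity, um^2/ms.
#' @param init Optional named starting vector; default is data-driven.
#' @param keep_chain Return the retained draws as `$chain`.
#' @return A `posterior_summary`: per-parameter posterior median, 2.5/97.5
#'   percentiles and split-Rhat, plus acceptance rate and sampler
#'   settings. Warns when any split-Rhat exceeds 1.05.
#' @export
fit_voxel <- function(data, protocol, n_samples = 10000,
                      burn_in = n_samples / 2, seed = NULL,
                      noise_sd = NULL, Db = 1.75, init = NULL,
                      keep_chain = FALSE) {
  data <- as.numeric(data)
  if (length(data) != nrow(protocol))
    .stopf("data length (%d) does not match protocol rows (%d)",
           length(data), nrow(protocol))
  if (any(!is.finite(data)) || all(data == 0))
    .stopf("degenerate data (non-finite or all-zero)")
  if (length(data) < 10 || length(unique(protocol$T)) < 2 ||
      length(unique(protocol$m)) < 2)
    .stopf("need >= 10 points spanning >= 2 encoding times and both FC and NC")
  if (!is.null(seed)) set.seed(seed)
  const <- .protocol_const(protocol, Db = Db)
  S0max <- 2 * max(data)
  lower <- c(.PRIOR_BOUNDS$D[1], .PRIOR_BOUNDS$f[1], .PRIOR_BOUNDS$v[1],
             log(.PRIOR_BOUNDS$tau[1]), 0)
  upper <- c(.PRIOR_BOUNDS$D[2], .PRIOR_BOUNDS$f[2], .PRIOR_BOUNDS$v[2],
             log(.PRIOR_BOUNDS$tau[2]), S0max)
  theta <- if (is.null(init)) .init_theta(data, protocol)
           else init[c("D", "f", "v", "tau", "S0")]
  z <- c(theta[["D"]], theta[["f"]], theta[["v"]], log(theta[["tau"]]),
         theta[["S0"]])
  z <- pmin(pmax(z, lower + 1e-9), upper - 1e-9)

  loglik <- function(rss) {
    if (is.null(noise_sd)) -(const$n / 2) * log(rss)
    else -rss / (2 * noise_sd^2)
  }
  # cached state
  tissue <- exp(-const$bD_fac * z[1])
  coef <- .phi2_coef(const, exp(z[4]))
  fp <- exp(-coef * z[3]^2 / 2)
  sig <- z[5] * ((1 - z[2]) * tissue + z[2] * fp * const$blood)
  rss <- sum((data - sig)^2)
  lp <- loglik(rss) + z[4]                  # + log tau Jacobian

  n_iter <- burn_in + n_samples
  scales <- c(0.15, 0.05, 0.4, 0.5, 0.05 * max(data))
  acc <- integer(5); acc_batch <- integer(5); batch_n <- 0L; batch_i <- 0L
  chain <- matrix(NA_real_, n_samples, 5)
  # joint adaptive-Metropolis kernel: the posterior has strong (f, v, tau)
  # correlations that componentwise moves traverse slowly, so from mid
  # burn-in onwards every sweep adds one joint proposal drawn from the
  # adapted empirical covariance of the chain
  recent <- matrix(NA_real_, 2000L, 5)
  r_ptr <- 0L; r_n <- 0L
  Lc <- NULL; s_am <- 1; am_acc <- 0L; am_try <- 0L
  refresh_cov <- function() {
    zz <- recent[seq_len(r_n), , drop = FALSE]
    S <- stats::cov(zz) + diag(1e-10, 5)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (!is.null(ch)) Lc <<- t(ch)
  }
  for (it in seq_len(n_iter)) {
    for (j in 1:5) {
      zj <- z[j] + scales[j] * stats::rnorm(1)
      if (zj < lower[j] || zj > upper[j]) next
      if (j == 1) {
        tissue2 <- exp(-const$bD_fac * zj)
        coef2 <- coef; fp2 <- fp
        sig2 <- z[5] * ((1 - z[2]) * tissue2 + z[2] * fp * const$blood)
      } else if (j == 2) {
        tissue2 <- tissue; coef2 <- coef; fp2 <- fp
        sig2 <- z[5] * ((1 - zj) * tissue + zj * fp * const$blood)
      } else if (j == 3) {
        tissue2 <- tissue; coef2 <- coef
        fp2 <- exp(-coef * zj^2 / 2)
        sig2 <- z[5] * ((1 - z[2]) * tissue + z[2] * fp2 * const$blood)
      } else if (j == 4) {
        tissue2 <- tissue
        coef2 <- .phi2_coef(const, exp(zj))
        fp2 <- exp(-coef2 * z[3]^2 / 2)
        sig2 <- z[5] * ((1 - z[2]) * tissue + z[2] * fp2 * const$blood)
      } else {
        tissue2 <- tissue; coef2 <- coef; fp2 <- fp
        sig2 <- (zj / z[5]) * sig
      }
      rss2 <- sum((data - sig2)^2)
      jac <- if (j == 4) zj else z[4]
      lp2 <- loglik(rss2) + jac
      if (log(stats::runif(1)) < lp2 - lp) {
        z[j] <- zj; tissue <- tissue2; coef <- coef2; fp <- fp2
        sig <- sig2; rss <- rss2; lp <- lp2
        acc[j] <- acc[j] + 1L; acc_batch[j] <- acc_batch[j] + 1L
      }
    }
    # record state for covariance adaptation
    r_ptr <- r_ptr %% 2000L + 1L
    recent[r_ptr, ] <- z
    r_n <- min(r_n + 1L, 2000L)
    if (it >= 400L && it %% 200L == 0L && it <= burn_in) refresh_cov()
    if (!is.null(Lc)) {
      zp <- z + s_am * as.numeric(Lc %*% stats::rnorm(5)) * 2.38 / sqrt(5)
      am_try <- am_try + 1L
      if (all(zp >= lower & zp <= upper)) {
        tissue2 <- exp(-const$bD_fac * zp[1])
        coef2 <- .phi2_coef(const, exp(zp[4]))
        fp2 <- exp(-coef2 * zp[3]^2 / 2)
        sig2 <- zp[5] * ((1 - zp[2]) * tissue2 + zp[2] * fp2 * const$blood)
        rss2 <- sum((data - sig2)^2)
        lp2 <- loglik(rss2) + zp[4]
        if (log(stats::runif(1)) < lp2 - lp) {
          z <- zp; tissue <- tissue2; coef <- coef2; fp <- fp2
          sig <- sig2; rss <- rss2; lp <- lp2
          am_acc <- am_acc + 1L
        }
      }
      if (it <= burn_in && am_try >= 100L) {
        s_am <- s_am * exp(min(0.2, 1 / sqrt(it / 100)) *
                             (am_acc / am_try - 0.234))
        am_acc <- 0L; am_try <- 0L
      }
    }
    batch_n <- batch_n + 1L
    if (it <= burn_in && batch_n == 50L) {
      batch_i <- batch_i + 1L
      step <- min(0.25, 1 / sqrt(batch_i))
      rate <- acc_batch / 50
      scales <- scales * exp(ifelse(rate > 0.44, step, -step))
      acc_batch[] <- 0L; batch_n <- 0L
    }
    if (it > burn_in) chain[it - burn_in, ] <- z
  }
  draws <- cbind(D = chain[, 1], f = chain[, 2], v = chain[, 3],
                 tau = exp(chain[, 4]), S0 = chain[, 5])
  qs <- apply(draws, 2, stats::quantile, probs = c(0.5, 0.025, 0.975),
              names = FALSE)
  rhat <- apply(chain, 2, .split_rhat)
  summary <- data.frame(parameter = colnames(draws),
                        median = qs[1, ], q2.5 = qs[2, ], q97.5 = qs[3, ],
                        rhat = rhat, row.names = NULL)
  if (any(is.finite(rhat) & rhat > 1.05))
    warning(sprintf("possible non-convergence: max split-Rhat = %.3f",
                    max(rhat, na.rm = TRUE)))
  structure(list(summary = summary,
                 acceptance = acc / n_iter,
                 n_samples = n_samples, burn_in = burn_in, seed = seed,
                 noise_sd = noise_sd, Db = Db,
                 chain = if (keep_chain) draws else NULL),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf(
    "<posterior_summary> %d draws after %d burn-in (mean acceptance %.2f)\n",
    x$n_samples, x$burn_in, mean(x$acceptance)))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Posterior medians of a fit
#'
#' @param object A `posterior_summary`.
#' @param ... Unused.
#' @return Named vector of posterior medians (D, f, v, tau, S0).
#' @export
coef.posterior_summary <- function(object, ...) {
  stats::setNames(object$summary$median, object$summary$parameter)
}

#' Fit the IVIM model voxel-wise over a volume
#'
#' Batch wrapper around [fit_voxel()]: each voxel of a 4-D volume (x, y,
#' z, protocol entry) or of a matrix (voxel, protocol entry) is fitted
#' independently; masked-out voxels are left as `NA` and never fitted.
#' Per-voxel seeds are derived deterministically from `seed`.
#'
#' @param volume 4-D array or voxels-by-entries matrix.
#' @param protocol Protocol data frame.
#' @param mask Optional logical array/vector over voxels.
#' @param seed Base RNG seed.
#' @param ... Passed to [fit_voxel()].
#' @return A list with one map per parameter (`median`), matching the
#'   spatial shape of the input, plus `lower`, `upper` (95 % interval) and
#'   `max_rhat` maps.
#' @export
fit_map <- function(volume, protocol, mask = NULL, seed = 1, ...) {
  if (is.matrix(volume)) {
    vox <- volume
    spatial_dim <- nrow(volume)
  } else if (length(dim(volume)) == 4L) {
    spatial_dim <- dim(volume)[1:3]
    vox <- matrix(volume, prod(spatial_dim), dim(volume)[4])
  } else .stopf("volume must be a matrix or a 4-D array")
  if (ncol(vox) != nrow(protocol))
    .stopf("volume 4th dimension (%d) does not match protocol rows (%d)",
           ncol(vox), nrow(protocol))
  n_vox <- nrow(vox)
  use <- if (is.null(mask)) rep(TRUE, n_vox) else as.logical(mask)
  if (length(use) != n_vox) .stopf("mask length does not match voxel count")
  pars <- c("D", "f", "v", "tau", "S0")
  med <- low <- upp <- matrix(NA_real_, n_vox, 5,
                              dimnames = list(NULL, pars))
  rh <- rep(NA_real_, n_vox)
  for (i in which(use)) {
    fit <- suppressWarnings(
      fit_voxel(vox[i, ], protocol, seed = seed + i, ...))
    s <- fit$summary
    med[i, s$parameter] <- s$median
    low[i, s$parameter] <- s$q2.5
    upp[i, s$parameter] <- s$q97.5
    rh[i] <- max(s$rhat, na.rm = TRUE)
  }
  shape <- function(m) {
    if (is.matrix(volume)) m
    else lapply(stats::setNames(pars, pars),
                function(p) array(m[, p], spatial_dim))
  }
  list(median = shape(med), lower = shape(low), upper = shape(upp),
       max_rhat = if (is.matrix(volume)) rh else array(rh, spatial_dim),
       parameters = pars, seed = seed)
}

#' Percentile bootstrap CI of the median
#'
#' @param values Numeric vector (n >= 2).
#' @param n_boot Bootstrap iterations.
#' @param seed RNG seed.
#' @param conf Confidence level.
#' @return List with `median`, `ci` (length-2 vector) and `n_boot`.
#' @export
bootstrap_median_ci <- function(values, n_boot = 10000, seed = NULL,
                                conf = 0.95) {
  values <- as.numeric(values)
  if (length(values) < 2) .stopf("need at least two values")
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  meds <- vapply(seq_len(n_boot), function(i)
    stats::median(values[sample.int(n, n, replace = TRUE)]), 0)
  a <- (1 - conf) / 2
  list(median = stats::median(values),
       ci = unname(stats::quantile(meds, c(a, 1 - a))),
       n_boot = n_boot)
}
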