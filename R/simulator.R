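# Monte-Carlo validation route: blood velocity simulated with the discrete
# (Euler-Maruyama) Langevin update, phase accrued against the dephasing
# factor, ensemble signal formed as the modulus of the complex mean.

#' One discrete Langevin velocity update
#'
#' `v(t + dt) = v(t) (1 - dt/tau) + sqrt(2 sigma_v^2 dt / tau) * xi`,
#' the Euler-Maruyama discretization of the Langevin equation. The
#' stationary distribution is Normal(0, sigma_v^2) up to O(dt/tau) and the
#' velocity autocorrelation decays as exp(-lag/tau).
#'
#' @param v Current velocity (mm/s); vectorized over walkers.
#' @param tau Correlation time, ms.
#' @param sigma_v Per-component stationary velocity SD, mm/s.
#' @param dt Time step, ms (`dt < tau`; larger steps make the
#'   discretization unstable and are rejected).
#' @param xi Standard-normal draw(s), same length as `v`.
#' @return Updated velocity (mm/s).
#' @export
step_velocity <- function(v, tau, sigma_v, dt, xi) {
  if (dt <= 0 || tau <= 0) .stopf("dt and tau must be positive")
  if (dt >= tau)
    .stopf("dt = %g ms >= tau = %g ms: unstable discretization", dt, tau)
  v * (1 - dt / tau) + sqrt(2 * sigma_v^2 * dt / tau) * xi
}

# exact integral of the piecewise-linear q over [t0, t1] (SI), from the
# cumulative integral at breakpoints
.q_step_integrals <- function(w, times) {
  qs <- .q_si(w)
  # q beyond the waveform end is zero; rule = 2 keeps the interpolant flat
  qv <- stats::approxfun(qs$t, qs$q, rule = 2)
  tm <- (times[-1] + times[-length(times)]) / 2
  h <- diff(times)
  # Simpson on each step is exact for quadratic Q (piecewise-linear q)
  (qv(times[-length(times)]) + 4 * qv(tm) + qv(times[-1])) * h / 6
}

#' Simulate walker phases under a gradient waveform
#'
#' Runs `n_walkers` independent 1-D Langevin velocity processes (the
#' component along the dephasing direction, which is the only one entering
#' the phase for linear encoding), with initial velocities drawn from the
#' stationary Normal(0, sigma_v^2) distribution, and accrues each walker's
#' phase `phi = -integral q(t) v(t) dt` with v held piecewise constant over
#' the simulation steps.
#'
#' @param w A [gradient_waveform()] (or a list of waveforms sharing the
#'   same encoding interval, which then share the identical velocity
#'   trajectories — useful to compare FC/NC or several b-values on the
#'   same ensemble).
#' @param tau Correlation time, ms.
#' @param sigma_v Per-component velocity SD, mm/s. For an isotropic flow
#'   with mean squared speed `v2bar`, `sigma_v = sqrt(v2bar/d)`.
#' @param n_walkers Number of walkers.
#' @param dt Time step, ms. If `dt > tau/20` it is refined to keep the
#'   Euler-Maruyama bias negligible, with a warning.
#' @param seed RNG seed (set for reproducibility when not `NULL`).
#' @param keep_velocities If `TRUE`, store the full velocity time series
#'   (memory heavy).
#' @return A `walker_ensemble`: phases in rad (matrix `n_walkers` x
#'   number-of-waveforms), simulation settings, and optionally velocities.
#' @export
simulate_phases <- function(w, tau, sigma_v, n_walkers = 20000, dt = 0.1,
                            seed = NULL, keep_velocities = FALSE) {
  ws <- if (inherits(w, "gradient_waveform")) list(w) else w
  stopifnot(all(vapply(ws, inherits, TRUE, "gradient_waveform")))
  if (dt > tau / 20) {
    dt_new <- tau / 20
    warning(sprintf(
      "dt = %g ms too coarse for tau = %g ms; refined to dt = %g ms",
      dt, tau, dt_new))
    dt <- dt_new
  }
  t_end <- max(vapply(ws, function(x) max(x$breakpoints), 0))
  n_steps <- ceiling(t_end / dt)
  times <- .ms(seq(0, by = dt, length.out = n_steps + 1))
  qint <- vapply(ws, .q_step_integrals, numeric(n_steps), times = times)
  qint <- matrix(qint, nrow = n_steps)
  if (!is.null(seed)) set.seed(seed)
  tau_s <- .ms(tau); dt_s <- .ms(dt)
  sig_si <- .mms(sigma_v)
  v <- stats::rnorm(n_walkers, 0, sig_si)
  phases <- matrix(0, n_walkers, length(ws))
  decay <- 1 - dt_s / tau_s
  kick <- sqrt(2 * sig_si^2 * dt_s / tau_s)
  vel <- if (keep_velocities)
    matrix(NA_real_, n_walkers, n_steps + 1) else NULL
  if (keep_velocities) vel[, 1] <- v
  for (i in seq_len(n_steps)) {
    # phase increment: v constant over the step, q integrated exactly
    phases <- phases - v %o% qint[i, ]
    v <- v * decay + kick * stats::rnorm(n_walkers)
    if (keep_velocities) vel[, i + 1] <- v
  }
  structure(list(phases = phases, n_walkers = n_walkers, dt = dt,
                 sigma_v = sigma_v, tau = tau, seed = seed,
                 labels = vapply(ws, function(x) x$label, ""),
                 velocities = vel),
            class = "walker_ensemble")
}

#' @export
print.walker_ensemble <- function(x, ...) {
  cat(sprintf(
    "<walker_ensemble> %d walkers, dt = %g ms, tau = %g ms, sigma_v = %g mm/s\n",
    x$n_walkers, x$dt, x$tau, x$sigma_v))
  s <- ensemble_signal(x)
  for (i in seq_along(x$labels))
    cat(sprintf("  F_P = %.5f (SE %.5f)  %s\n", s$fp[i], s$se[i], x$labels[i]))
  invisible(x)
}

#' Ensemble signal of simulated phases
#'
#' `F_P = | mean_j exp(i phi_j) |`, the modulus of the complex ensemble
#' mean (mirroring magnitude MRI; for the zero-mean symmetric phase
#' distributions generated here the imaginary part vanishes in
#' expectation). The Monte-Carlo standard error is estimated by a
#' `n_folds`-fold walker jackknife.
#'
#' The modulus estimator carries a finite-ensemble noise floor of order
#' `1/sqrt(2 n_walkers)`: when the true attenuation is below the floor, the
#' modulus of the complex mean is positively biased, exactly as a magnitude
#' MR image is Rician-floored at low SNR. For unbiased comparisons against
#' analytical predictions the mean cosine `fp_cos = mean(cos(phi))` is also
#' returned (the phases are zero-mean symmetric, so the sine part carries
#' no signal), with its exact iid standard error.
#'
#' @param e A `walker_ensemble` from [simulate_phases()].
#' @param n_folds Number of jackknife folds.
#' @return A data frame with columns `label`, `fp` (modulus), `se`
#'   (jackknife), `fp_cos` (mean cosine) and `se_cos`.
#' @export
ensemble_signal <- function(e, n_folds = 20) {
  stopifnot(inherits(e, "walker_ensemble"))
  ph <- e$phases
  fold <- rep_len(seq_len(n_folds), nrow(ph))
  out <- lapply(seq_len(ncol(ph)), function(j) {
    z <- complex(real = cos(ph[, j]), imaginary = sin(ph[, j]))
    fp <- Mod(mean(z))
    # leave-one-fold-out estimates
    tot <- sum(z); n <- length(z)
    loo <- vapply(seq_len(n_folds), function(k) {
      sel <- fold == k
      Mod((tot - sum(z[sel])) / (n - sum(sel)))
    }, 0)
    se <- sqrt((n_folds - 1) / n_folds * sum((loo - mean(loo))^2))
    c(fp = fp, se = se, fp_cos = mean(Re(z)),
      se_cos = stats::sd(Re(z)) / sqrt(n))
  })
  out <- do.call(rbind, out)
  data.frame(label = e$labels, fp = out[, "fp"], se = out[, "se"],
             fp_cos = out[, "fp_cos"], se_cos = out[, "se_cos"],
             row.names = NULL)
}
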