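# Desk-scale reproductions of the simulation studies: FC/NC regime
# convergence, analytic-vs-Monte-Carlo agreement curves, and the SNR
# robustness sweep of the Bayesian fit.

#' FC/NC convergence scan over T/tau
#'
#' Evaluates the closed-form FC and NC perfusion attenuations at a fixed
#' b-value across a grid of encoding-time-to-correlation-time ratios
#' (fixed tau, varying T) and reports the smallest ratio at which the
#' relative FC-NC signal difference falls below `threshold` — the point
#' where the pseudodiffusive regime is effectively reached and flow
#' compensation stops mattering.
#'
#' @param sigma_v Per-component velocity SD, mm/s.
#' @param delta,Delta Lobe timing, ms.
#' @param b b-value at which the contrast is evaluated, s/mm^2.
#' @param tau Correlation time held fixed, ms.
#' @param ratios Grid of T/tau values (each T = ratio * tau must satisfy
#'   the DDE timing constraint).
#' @param threshold Relative-difference threshold defining convergence.
#' @return List with `table` (ratio, fp_fc, fp_nc, rel_diff) and
#'   `convergence_point` (smallest grid ratio with rel_diff < threshold).
#' @export
regime_convergence_scan <- function(sigma_v = 1.5, delta = 8.6, Delta = 10,
                                    b = 200, tau = 200,
                                    ratios = seq(0.5, 20, by = 0.05),
                                    threshold = 0.05) {
  Tmin <- 2 * (Delta + delta)
  if (any(ratios * tau < Tmin))
    .stopf("smallest T = %g ms violates the DDE timing bound %g ms",
           min(ratios) * tau, Tmin)
  p <- ivim_params(f = 1, D = 0, v = sqrt(3) * sigma_v, tau = tau)
  G <- strength_for_b(b, delta, Delta)
  fp_nc <- fp_closed_form(p, G, delta, Delta, ratios * tau, +1)
  fp_fc <- fp_closed_form(p, G, delta, Delta, ratios * tau, -1)
  rel <- abs(fp_fc - fp_nc) / fp_nc
  conv <- ratios[rel < threshold]
  list(table = data.frame(ratio = ratios, fp_fc = fp_fc, fp_nc = fp_nc,
                          rel_diff = rel),
       convergence_point = if (length(conv)) min(conv) else NA_real_,
       threshold = threshold, b = b, tau = tau)
}

#' Analytic and simulated perfusion-attenuation curves
#'
#' Generates the three standard validation panels: F_P versus b at fixed
#' T/tau, versus T/tau at fixed tau (varying T), and versus T/tau at fixed
#' T (varying tau), for FC and NC, with optional Langevin-simulation
#' markers overlaid on the analytic curves.
#'
#' @param sigma_v Per-component velocity SD, mm/s.
#' @param delta,Delta Lobe timing, ms.
#' @param b_fixed b-value for the T/tau panels, s/mm^2.
#' @param T_panel_a,tau_panel_a Encoding time and correlation time of the
#'   b-sweep panel (their ratio is the panel's T/tau).
#' @param tau_panel_b Fixed tau of the varying-T panel, ms.
#' @param T_panel_c Fixed T of the varying-tau panel, ms.
#' @param simulate Add Monte-Carlo markers.
#' @param n_walkers,dt,seed Simulation settings (see [simulate_phases()]).
#' @return List of data frames `panel_a`, `panel_b`, `panel_c` (analytic
#'   curves; simulation columns `fp_sim`, `se_sim`, `fp_cos`, `se_cos`
#'   where requested).
#' @export
figure_curves <- function(sigma_v = 1.5, delta = 8.6, Delta = 10,
                          b_fixed = 100, T_panel_a = 80, tau_panel_a = 200,
                          tau_panel_b = 200, T_panel_c = 50,
                          simulate = FALSE, n_walkers = 20000, dt = 0.1,
                          seed = 1) {
  v <- sqrt(3) * sigma_v
  pa <- function(tau) ivim_params(f = 1, D = 0, v = v, tau = tau)
  Tmin <- 2 * (Delta + delta)
  bs <- seq(0, 200, by = 10)
  G <- strength_for_b(bs, delta, Delta)
  panel_a <- data.frame(
    b = rep(bs, 2), m = rep(c(1, -1), each = length(bs)),
    ratio = T_panel_a / tau_panel_a,
    fp = fp_closed_form(pa(tau_panel_a), rep(G, 2), delta, Delta,
                        T_panel_a, rep(c(1, -1), each = length(bs))))
  ratios_b <- seq(max(0.2, Tmin / tau_panel_b), 3, by = 0.05)
  Gb <- strength_for_b(b_fixed, delta, Delta)
  panel_b <- data.frame(
    ratio = rep(ratios_b, 2),
    m = rep(c(1, -1), each = length(ratios_b)),
    fp = fp_closed_form(pa(tau_panel_b), Gb, delta, Delta,
                        rep(ratios_b * tau_panel_b, 2),
                        rep(c(1, -1), each = length(ratios_b))))
  ratios_c <- exp(seq(log(0.1), log(20), length.out = 80))
  panel_c <- do.call(rbind, lapply(c(1, -1), function(m)
    data.frame(ratio = ratios_c, m = m,
               fp = vapply(ratios_c, function(r)
                 fp_closed_form(pa(T_panel_c / r), Gb, delta, Delta,
                                T_panel_c, m), 0))))
  out <- list(panel_a = panel_a, panel_b = panel_b, panel_c = panel_c)
  if (simulate) {
    bs_sim <- c(5, 10, 20, 30, 50, 100, 150, 200)
    ws <- lapply(c(1, -1), function(m) lapply(bs_sim, function(b)
      make_dde(strength_for_b(b, delta, Delta), delta, Delta, T_panel_a,
               flow_compensated = m < 0)))
    e <- simulate_phases(c(ws[[1]], ws[[2]]), tau_panel_a, sigma_v,
                         n_walkers = n_walkers, dt = dt, seed = seed)
    s <- ensemble_signal(e)
    out$panel_a_sim <- data.frame(
      b = rep(bs_sim, 2), m = rep(c(1, -1), each = length(bs_sim)),
      fp_sim = s$fp, se_sim = s$se, fp_cos = s$fp_cos, se_cos = s$se_cos)
  }
  out
}

#' SNR robustness sweep of the Bayesian fit
#'
#' For each flow regime and SNR level, generates `n_voxels` synthetic
#' voxels under the default FC/NC multi-T protocol, fits each voxel by
#' MCMC, and tabulates the median estimate, median bias and interquartile
#' range of every parameter.
#'
#' @param regimes Subset of `"diffusive"`, `"intermediate"`,
#'   `"ballistic"` (see [regime_params()]).
#' @param snr_levels Post-averaging SNR values.
#' @param n_voxels Voxels per condition.
#' @param protocol Acquisition protocol.
#' @param n_samples,burn_in MCMC settings per voxel (see [fit_voxel()]).
#' @param seed Base seed; every (regime, SNR, voxel) combination derives
#'   its own seed deterministically.
#' @param params_fun Function regime -> [ivim_params()]; defaults to
#'   [regime_params()].
#' @return Data frame with one row per (regime, snr, parameter):
#'   truth, median estimate, median bias, IQR bounds.
#' @export
snr_sweep <- function(regimes = c("diffusive", "intermediate", "ballistic"),
                      snr_levels = c(20, 50, 200, 2000), n_voxels = 100,
                      protocol = default_protocol(), n_samples = 5000,
                      burn_in = 2500, seed = 1,
                      params_fun = regime_params) {
  out <- list()
  pars <- c("D", "f", "v", "tau", "S0")
  for (ri in seq_along(regimes)) {
    regime <- regimes[ri]
    p <- params_fun(regime)
    truth <- c(D = p$D, f = p$f, v = p$v, tau = p$tau, S0 = p$S0)
    for (si in seq_along(snr_levels)) {
      snr <- snr_levels[si]
      vox <- synthetic_voxels(p, protocol, snr, n_voxels,
                              seed = seed + 1000L * ri + 10L * si)
      est <- matrix(NA_real_, n_voxels, 5, dimnames = list(NULL, pars))
      for (i in seq_len(n_voxels)) {
        fit <- suppressWarnings(fit_voxel(
          vox[i, ], protocol, n_samples = n_samples, burn_in = burn_in,
          seed = seed + 100000L * ri + 10000L * si + i))
        est[i, ] <- coef(fit)[pars]
      }
      for (pp in pars) {
        qs <- stats::quantile(est[, pp], c(0.25, 0.5, 0.75), names = FALSE)
        out[[length(out) + 1L]] <- data.frame(
          regime = regime, snr = snr, parameter = pp,
          truth = truth[[pp]], median_est = qs[2],
          median_bias = qs[2] - truth[[pp]],
          q25 = qs[1], q75 = qs[3], n_voxels = n_voxels)
      }
    }
  }
  do.call(rbind, out)
}
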