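# Synthetic FC/NC multi-encoding-time IVIM data generation: the in-vivo
# style acquisition protocol, noise-free forward signals, Rician noise, and
# geometric direction averaging.

#' Default FC/NC multi-T acquisition protocol
#'
#' The brain acquisition emulated by the synthetic-data module: b-values
#' 0, 5, 10, 20, 30, 100, 200 s/mm^2 (acquired order 0, 200, 5, 100, 10,
#' 30, 20), encoding times T = 50, 60, 85, 100 ms, both FC and NC
#' polarities, lobe duration delta = 8.6 ms, lobe separation Delta = 10 ms
#' and six diffusion encoding directions whose signals are geometrically
#' averaged: 7 x 4 x 2 = 56 signal samples per voxel.
#'
#' @param b b-values in s/mm^2.
#' @param T_ms Encoding times in ms.
#' @param delta,Delta Lobe timing in ms.
#' @param n_directions Number of encoding directions averaged per sample.
#' @return A data frame of class `acquisition_protocol` with columns `b`,
#'   `T`, `m` and attributes `delta`, `Delta`, `n_directions`,
#'   `n_b0_repeats`.
#' @export
default_protocol <- function(b = c(0, 200, 5, 100, 10, 30, 20),
                             T_ms = c(50, 60, 85, 100),
                             delta = 8.6, Delta = 10, n_directions = 6) {
  if (any(b < 0)) .stopf("b-values must be >= 0")
  if (!0 %in% b) .stopf("every (T, m) block needs a b = 0 entry")
  if (any(T_ms < 2 * (Delta + delta)))
    .stopf("all T must be >= 2*(Delta+delta) = %g ms", 2 * (Delta + delta))
  grid <- expand.grid(b = b, m = c(+1, -1), T = T_ms,
                      KEEP.OUT.ATTRS = FALSE)
  pro <- data.frame(b = grid$b, T = grid$T, m = grid$m)
  attr(pro, "delta") <- delta
  attr(pro, "Delta") <- Delta
  attr(pro, "n_directions") <- n_directions
  attr(pro, "n_b0_repeats") <- n_directions
  class(pro) <- c("acquisition_protocol", "data.frame")
  pro
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat(sprintf(
    "<acquisition_protocol> %d entries: %d b-values x %d T x FC/NC\n",
    nrow(x), length(unique(x$b)), length(unique(x$T))))
  cat(sprintf("  delta = %g ms, Delta = %g ms, %d directions\n",
              attr(x, "delta"), attr(x, "Delta"), attr(x, "n_directions")))
  print(as.data.frame(utils::head(x, 8)))
  if (nrow(x) > 8) cat(sprintf("  ... %d more rows\n", nrow(x) - 8L))
  invisible(x)
}

#' Noise-free synthetic dataset
#'
#' Forward-simulates one voxel's signal for every protocol entry from the
#' two-compartment model with the closed-form DDE perfusion attenuation.
#'
#' @param p An [ivim_params()].
#' @param protocol An [default_protocol()]-style protocol.
#' @return Numeric vector of signals (one per protocol row) with the
#'   generating parameters and protocol attached as attributes.
#' @export
noisefree_dataset <- function(p, protocol) {
  s <- ivim_signal(p, protocol)
  attr(s, "params") <- p
  attr(s, "protocol") <- protocol
  s
}

#' Add Rician noise
#'
#' Magnitude-MRI noise: `sqrt((S + sigma X)^2 + (sigma Y)^2)` with
#' independent standard normal X, Y and `sigma = S0/snr`. The SNR is
#' defined on the b = 0 signal after direction averaging, matching how an
#' in vivo SNR map is computed from repeated b = 0 images.
#'
#' @param signal Noise-free signal vector (or matrix voxels x entries).
#' @param snr Signal-to-noise ratio at b = 0.
#' @param seed RNG seed (optional).
#' @param S0 Reference signal defining the noise level; defaults to the
#'   `S0` of the generating parameters attached to `signal`, else 1.
#' @return Noisy signal, same shape as `signal`.
#' @export
add_rician <- function(signal, snr, seed = NULL, S0 = NULL) {
  if (snr <= 0) .stopf("snr must be positive")
  if (is.null(S0)) {
    pp <- attr(signal, "params")
    S0 <- if (!is.null(pp)) pp$S0 else 1
  }
  if (!is.null(seed)) set.seed(seed)
  sigma <- S0 / snr
  n <- length(signal)
  out <- sqrt((signal + sigma * stats::rnorm(n))^2 +
                (sigma * stats::rnorm(n))^2)
  attributes(out) <- attributes(signal)
  attr(out, "snr") <- snr
  attr(out, "seed") <- seed
  out
}

#' Regime-representative parameter sets
#'
#' Brain-like IVIM parameters with the correlation time set to probe the
#' diffusive (tau = 10 ms), intermediate (tau = 130 ms) or ballistic
#' (tau = 800 ms) flow regime. The shared defaults f = 4.75 %,
#' D = 0.91 um^2/ms, v = 1.51 mm/s, S0 = 1 are typical healthy-brain
#' values.
#'
#' @param regime `"diffusive"`, `"intermediate"` or `"ballistic"`.
#' @param f,D,v,S0,Db Overridable shared parameters, see [ivim_params()].
#' @return An [ivim_params()].
#' @export
regime_params <- function(regime = c("intermediate", "diffusive",
                                     "ballistic"),
                          f = 0.0475, D = 0.91, v = 1.51, S0 = 1,
                          Db = 1.75) {
  regime <- match.arg(regime)
  tau <- c(diffusive = 10, intermediate = 130, ballistic = 800)[[regime]]
  ivim_params(f = f, D = D, v = v, tau = tau, S0 = S0, Db = Db)
}

#' Geometric direction averaging
#'
#' Averages diffusion-weighted signals across encoding directions by the
#' geometric mean. For the isotropic synthetic model all directions share
#' the same expectation, so on noise-free input the operation is the
#' identity; on noisy input it improves the effective SNR by about
#' `sqrt(n_directions)`.
#'
#' @param signals Matrix (directions x entries) or a vector of one
#'   signal's replicates across directions; all values positive.
#' @return Vector of geometric means over directions (a scalar for vector
#'   input).
#' @export
direction_average <- function(signals) {
  m <- if (is.matrix(signals)) signals else matrix(signals, ncol = 1)
  if (any(m <= 0)) .stopf("geometric averaging requires positive signals")
  exp(colMeans(log(m)))
}

#' Per-direction Rician noise followed by geometric averaging
#'
#' Slow-path noise model: each of `n_directions` replicate acquisitions
#' receives independent Rician noise at the per-direction level
#' `sigma_dir = sqrt(n_directions) * S0 / snr` (so that the stated `snr`
#' is the effective post-averaging value), and the replicates are then
#' geometrically averaged. The fast path ([add_rician()]) applies the
#' post-averaging noise directly.
#'
#' @inheritParams add_rician
#' @param n_directions Number of directions to simulate and average.
#' @return Averaged noisy signal vector.
#' @export
add_rician_directions <- function(signal, snr, n_directions = 6,
                                  seed = NULL, S0 = NULL) {
  if (is.null(S0)) {
    pp <- attr(signal, "params")
    S0 <- if (!is.null(pp)) pp$S0 else 1
  }
  if (!is.null(seed)) set.seed(seed)
  sigma <- sqrt(n_directions) * S0 / snr
  reps <- matrix(rep(as.numeric(signal), each = n_directions),
                 n_directions, length(signal))
  noisy <- sqrt((reps + sigma * matrix(stats::rnorm(length(reps)),
                                       nrow(reps)))^2 +
                (sigma * matrix(stats::rnorm(length(reps)), nrow(reps)))^2)
  out <- direction_average(noisy)
  attributes(out) <- attributes(signal)
  attr(out, "snr") <- snr
  out
}

#' Generate a cohort of noisy synthetic voxels
#'
#' Convenience wrapper: one noise-free signal from `p`, replicated over
#' `n_voxels` with independent Rician noise at the stated (post-averaging)
#' SNR.
#'
#' @param p An [ivim_params()].
#' @param protocol Protocol data frame.
#' @param snr Post-averaging SNR at b = 0.
#' @param n_voxels Number of voxels.
#' @param seed RNG seed.
#' @return Matrix `n_voxels` x `nrow(protocol)` with metadata attributes
#'   (`params`, `snr`, `seed`).
#' @export
synthetic_voxels <- function(p, protocol, snr, n_voxels, seed = NULL) {
  clean <- noisefree_dataset(p, protocol)
  if (!is.null(seed)) set.seed(seed)
  sigma <- p$S0 / snr
  n <- nrow(protocol)
  noisy <- matrix(rep(clean, each = n_voxels), n_voxels, n)
  noisy <- sqrt((noisy + sigma * matrix(stats::rnorm(n_voxels * n),
                                        n_voxels, n))^2 +
                (sigma * matrix(stats::rnorm(n_voxels * n),
                                n_voxels, n))^2)
  attr(noisy, "params") <- p
  attr(noisy, "protocol") <- protocol
  attr(noisy, "snr") <- snr
  attr(noisy, "seed") <- seed
  noisy
}
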