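#' Velocity autocorrelation functions
#'
#' Scalar velocity autocorrelation function (VACF) descriptors used by the
#' phase-variance engines. The scalar VACF for isotropic `d`-dimensional
#' flow is `<v(t) v(t')> / d`, so the mean squared speed `v2bar` always
#' enters the phase variance divided by `d`.
#'
#' Kinds:
#' * `"exponential"`: `(v2bar/d) exp(-|t - t'|/tau)` — the Langevin
#'   (Ornstein-Uhlenbeck) flow model; the basis of the closed-form DDE model.
#' * `"constant"`: `(v2bar/d)` — ballistic flow; the phase variance reduces
#'   to `c^2 v2bar / d`.
#' * `"linear"`: `(v2bar/d) max(0, 1 - |t - t'|/tau)` — straight capillary
#'   segments of equal transit time; supported by the numerical engine only.
#'
#' @param kind One of `"exponential"`, `"constant"`, `"linear"`.
#' @param v2bar Mean squared speed in mm^2/s^2 (`v2bar >= 0`). For
#'   isotropic flow with per-component dispersion `sigma_v`,
#'   `v2bar = d * sigma_v^2`.
#' @param tau Correlation time in ms (required for `"exponential"` and
#'   `"linear"`).
#' @param d Flow dimensionality (1, 2 or 3).
#' @return An object of class `vacf`.
#' @export
vacf <- function(kind = c("exponential", "constant", "linear"),
                 v2bar, tau = NA_real_, d = 3) {
  kind <- match.arg(kind)
  if (!is.finite(v2bar) || v2bar < 0) .stopf("v2bar must be >= 0")
  if (!d %in% c(1, 2, 3)) .stopf("d must be 1, 2 or 3")
  if (kind %in% c("exponential", "linear") && (!is.finite(tau) || tau <= 0))
    .stopf("tau must be > 0 ms for the %s VACF", kind)
  structure(list(kind = kind, v2bar = v2bar, tau = tau, d = d),
            class = "vacf")
}

#' @export
print.vacf <- function(x, ...) {
  cat(sprintf("<vacf> %s: v2bar = %g mm2/s2, tau = %g ms, d = %d\n",
              x$kind, x$v2bar, x$tau, as.integer(x$d)))
  invisible(x)
}
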