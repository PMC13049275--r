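#' Gradient waveform objects
#'
#' A `gradient_waveform` represents the *effective* diffusion-encoding
#' gradient of a spin-echo experiment as a piecewise-constant function of
#' time: the sign flip imposed by the refocusing pulse is absorbed into the
#' stored amplitudes, so the waveform integrates to zero directly (the
#' rephasing condition) and the dephasing factor q(t) is a plain integral.
#'
#' @param breakpoints Strictly increasing times in ms partitioning the
#'   encoding interval; the waveform is constant between consecutive
#'   breakpoints.
#' @param amplitudes Effective gradient amplitude (mT/m, signed) on each
#'   interval; `length(amplitudes) == length(breakpoints) - 1`.
#' @param delta,Delta,T,m,G,label Optional metadata (lobe duration,
#'   lobe separation and encoding time in ms; polarity flag; nominal
#'   amplitude in mT/m; free-text label) attached by the constructors.
#'
#' @return An object of class `gradient_waveform`.
#' @seealso [make_dde()], [make_bipolar()], [dephasing()], [bvalue()],
#'   [cvalue()]
#' @export
gradient_waveform <- function(breakpoints, amplitudes, delta = NA_real_,
                              Delta = NA_real_, T = NA_real_, m = NA_real_,
                              G = NA_real_, label = "") {
  breakpoints <- as.numeric(breakpoints)
  amplitudes <- as.numeric(amplitudes)
  if (length(breakpoints) < 2L)
    .stopf("a waveform needs at least two breakpoints")
  if (any(diff(breakpoints) <= 0))
    .stopf("breakpoints must be strictly increasing")
  if (length(amplitudes) != length(breakpoints) - 1L)
    .stopf("need one amplitude per interval (%d), got %d",
           length(breakpoints) - 1L, length(amplitudes))
  if (any(!is.finite(amplitudes)))
    .stopf("amplitudes must be finite")
  area <- sum(amplitudes * diff(breakpoints))
  scale <- max(abs(amplitudes) * diff(breakpoints), 1e-300)
  if (abs(area) > 1e-9 * max(scale))
    .stopf("waveform violates the rephasing condition: integral G dt = %g", area)
  structure(list(breakpoints = breakpoints, amplitudes = amplitudes,
                 delta = delta, Delta = Delta, T = T, m = m, G = G,
                 label = label),
            class = "gradient_waveform")
}

#' @export
print.gradient_waveform <- function(x, ...) {
  cat(sprintf("<gradient_waveform> %s\n", x$label))
  cat(sprintf("  segments: %d over [%.3f, %.3f] ms\n",
              length(x$amplitudes), min(x$breakpoints), max(x$breakpoints)))
  if (!is.na(x$T))
    cat(sprintf("  G = %.3f mT/m, delta = %.2f ms, Delta = %.2f ms, T = %.2f ms, m = %+d\n",
                x$G, x$delta, x$Delta, x$T, as.integer(x$m)))
  cat(sprintf("  b = %.4g s/mm2, c = %.4g s/mm\n", bvalue(x), cvalue(x)))
  invisible(x)
}

# drop zero-length intervals and merge equal neighbouring amplitudes
.clean_segments <- function(bp, amp) {
  keep <- diff(bp) > 0
  bp2 <- c(bp[1L], bp[-1L][keep])
  amp2 <- amp[keep]
  i <- 1L
  while (i < length(amp2)) {
    if (amp2[i] == amp2[i + 1L]) {
      amp2 <- amp2[-(i + 1L)]
      bp2 <- bp2[-(i + 1L)]
    } else i <- i + 1L
  }
  list(bp = bp2, amp = amp2)
}

#' Construct a double diffusion encoding (DDE) waveform
#'
#' Builds the effective gradient of a single-refocused DDE sequence: two
#' bipolar gradient pairs, the first starting at t = 0 and the second ending
#' at the encoding time `T` (defined first-lobe start to last-lobe end).
#' Any free time for `T > 2*(Delta + delta)` is placed between the two pairs,
#' symmetric about the refocusing pulse. Flow compensation is obtained by
#' inverting the polarity of the second bipolar pair, which nulls the first
#' gradient moment; in effective-gradient terms the non-compensated (NC)
#' waveform has both pairs with the same polarity (`m = +1`) and the
#' flow-compensated (FC) waveform has the second pair negated (`m = -1`).
#'
#' The first lobe is stored with negative effective polarity so that the
#' flow-weighting factor `c = -integral(q)` is nonnegative for NC; only
#' `c^2` enters any model, so the choice is purely a reporting convention.
#'
#' @param G Gradient amplitude in mT/m (`G >= 0`; `G = 0` gives a b = 0
#'   measurement with an all-zero waveform of the same timing).
#' @param delta Gradient lobe duration in ms.
#' @param Delta Lobe separation (onset-to-onset within a pair) in ms;
#'   `delta <= Delta`.
#' @param T Encoding time in ms; must satisfy `T >= 2*(Delta + delta)`.
#' @param flow_compensated Logical; `TRUE` for FC (`m = -1`).
#' @param label Optional label.
#'
#' @return A [gradient_waveform()].
#' @examples
#' w <- make_dde(30, delta = 8.6, Delta = 10, T = 50)
#' bvalue(w)
#' cvalue(w)
#' @export
make_dde <- function(G, delta, Delta, T, flow_compensated = FALSE,
                     label = NULL) {
  if (!is.finite(G) || G < 0) .stopf("G must be >= 0 (mT/m), got %g", G)
  if (delta <= 0 || Delta <= 0) .stopf("delta and Delta must be positive")
  if (delta > Delta)
    .stopf("timing violation: delta (%g ms) exceeds Delta (%g ms)", delta, Delta)
  if (T < 2 * (Delta + delta))
    .stopf("timing violation: T = %g ms is shorter than 2*(Delta+delta) = %g ms",
           T, 2 * (Delta + delta))
  m <- if (flow_compensated) -1 else +1
  a2 <- T - Delta - delta       # onset of the second pair
  s2 <- m                       # relative polarity of the second pair
  bp <- c(0, delta, Delta, Delta + delta,
          a2, a2 + delta, a2 + Delta, T)
  amp <- c(-G, 0, +G, 0, -s2 * G, 0, +s2 * G)
  seg <- .clean_segments(bp, amp)
  if (is.null(label))
    label <- sprintf("DDE %s: G=%.3g mT/m, delta=%.3g, Delta=%.3g, T=%.3g ms",
                     if (flow_compensated) "FC" else "NC", G, delta, Delta, T)
  gradient_waveform(seg$bp, seg$amp, delta = delta, Delta = Delta, T = T,
                    m = m, G = G, label = label)
}

#' Construct a single bipolar pair (PGSE analogue)
#'
#' One bipolar gradient pair with the same lobe timing as half a DDE
#' waveform. Used for cross-checks of the phase-variance engine: for an
#' exponential velocity autocorrelation the DDE phase variance with the
#' pair-coupling term removed is exactly twice the single-pair value.
#'
#' @inheritParams make_dde
#' @return A [gradient_waveform()].
#' @export
make_bipolar <- function(G, delta, Delta, label = NULL) {
  if (!is.finite(G) || G < 0) .stopf("G must be >= 0 (mT/m), got %g", G)
  if (delta <= 0 || Delta <= 0) .stopf("delta and Delta must be positive")
  if (delta > Delta)
    .stopf("timing violation: delta (%g ms) exceeds Delta (%g ms)", delta, Delta)
  bp <- c(0, delta, Delta, Delta + delta)
  amp <- c(-G, 0, +G)
  seg <- .clean_segments(bp, amp)
  if (is.null(label))
    label <- sprintf("bipolar pair: G=%.3g mT/m, delta=%.3g, Delta=%.3g ms",
                     G, delta, Delta)
  gradient_waveform(seg$bp, seg$amp, delta = delta, Delta = Delta,
                    T = Delta + delta, m = NA_real_, G = G, label = label)
}

# piecewise-linear q(t) in SI units: breakpoint times (s), q at breakpoints
# (rad/m) and the slope gamma*G (rad m^-1 s^-1) on each segment
.q_si <- function(w) {
  t_s <- .ms(w$breakpoints)
  slope <- GAMMA_1H * .mTm(w$amplitudes)
  q <- c(0, cumsum(slope * diff(t_s)))
  # the rephasing condition makes q vanish at the end up to rounding
  q[length(q)] <- 0
  list(t = t_s, q = q, slope = slope)
}

#' Dephasing factor q(t) of a waveform
#'
#' Integrates the effective gradient to the dephasing factor
#' `q(t) = gamma * integral_0^t G(t') dt'`. For a valid (rephased) waveform
#' q is continuous, piecewise linear, and vanishes at both ends; its
#' extrema therefore occur at breakpoints.
#'
#' @param w A [gradient_waveform()].
#' @return An object of class `dephasing` with elements `t_ms`
#'   (breakpoint times), `q_rad_per_mm` (q at breakpoints) and
#'   `slope_rad_per_mm_ms` (slope on each segment).
#' @export
dephasing <- function(w) {
  stopifnot(inherits(w, "gradient_waveform"))
  qs <- .q_si(w)
  structure(list(t_ms = w$breakpoints,
                 q_rad_per_mm = qs$q / 1e3,
                 slope_rad_per_mm_ms = qs$slope / 1e6,
                 waveform = w),
            class = "dephasing")
}

#' @export
print.dephasing <- function(x, ...) {
  cat("<dephasing> q(t), piecewise linear\n")
  print(data.frame(t_ms = x$t_ms, q_rad_per_mm = x$q_rad_per_mm))
  invisible(x)
}

#' b-value of a waveform
#'
#' Diffusion weighting `b = integral q(t)^2 dt`, evaluated exactly segment
#' by segment (q is piecewise linear). For a DDE waveform this equals the
#' closed form `2 gamma^2 G^2 delta^2 (Delta - delta/3)` and is identical
#' for FC and NC.
#'
#' @param w A [gradient_waveform()].
#' @return b-value in s/mm^2.
#' @export
bvalue <- function(w) {
  qs <- .q_si(w)
  dt <- diff(qs$t)
  q0 <- qs$q[-length(qs$q)]
  s <- qs$slope
  # integral of (q0 + s u)^2 over u in [0, dt]
  b_si <- sum(dt * (q0^2 + q0 * s * dt + s^2 * dt^2 / 3))
  .b_user(b_si)
}

#' Flow-weighting factor c of a waveform
#'
#' The first-moment sensitivity `c = -integral q(t) dt`, in s/mm. `c` is
#' zero for flow-compensated waveforms and `2 gamma G delta Delta` for the
#' NC DDE waveform (nonnegative under the stored sign convention).
#'
#' @param w A [gradient_waveform()].
#' @return c-value in s/mm.
#' @export
cvalue <- function(w) {
  qs <- .q_si(w)
  dt <- diff(qs$t)
  qmid <- (qs$q[-1] + qs$q[-length(qs$q)]) / 2
  .c_user(-sum(qmid * dt))
}

#' Gradient strength for a target b-value
#'
#' Inverts the DDE b-value closed form:
#' `G = sqrt(b / (2 gamma^2 delta^2 (Delta - delta/3)))`.
#'
#' @param b Target b-value in s/mm^2 (`b >= 0`).
#' @param delta,Delta Lobe duration and separation in ms.
#' @return Gradient amplitude in mT/m.
#' @export
strength_for_b <- function(b, delta, Delta) {
  if (any(b < 0)) .stopf("b must be >= 0")
  if (delta <= 0 || Delta <= 0 || delta > Delta)
    .stopf("need 0 < delta <= Delta")
  d_s <- .ms(delta); D_s <- .ms(Delta)
  G_si <- sqrt(.b_si(b) / (2 * GAMMA_1H^2 * d_s^2 * (D_s - d_s / 3)))
  G_si / 1e-3
}

#' Write / read a gradient waveform as plain text
#'
#' Serializes a waveform as a YAML header (prefixed with `#`) carrying the
#' metadata (G, delta, Delta, T, m, label) followed by a two-column table
#' `time_ms gradient_mT_per_m` listing each segment start and its amplitude,
#' with a final row at the end time.
#'
#' @param w A [gradient_waveform()].
#' @param path File path.
#' @return `write_waveform` returns `path` invisibly; `read_waveform`
#'   returns the reconstructed [gradient_waveform()].
#' @export
write_waveform <- function(w, path) {
  meta <- list(G = w$G, delta = w$delta, Delta = w$Delta, T = w$T,
               m = w$m, label = w$label)
  hdr <- strsplit(yaml::as.yaml(meta), "\n")[[1]]
  n <- length(w$amplitudes)
  tab <- data.frame(time_ms = w$breakpoints,
                    gradient_mT_per_m = c(w$amplitudes, 0))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", hdr), con)
  writeLines("time_ms\tgradient_mT_per_m", con)
  utils::write.table(tab, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  lines <- readLines(path)
  hdr <- sub("^# ?", "", grep("^#", lines, value = TRUE))
  meta <- yaml::yaml.load(paste(hdr, collapse = "\n"))
  body <- lines[!grepl("^#", lines)][-1L]  # drop column header
  tab <- utils::read.table(text = body, sep = "\t",
                           col.names = c("time_ms", "gradient_mT_per_m"))
  n <- nrow(tab)
  gradient_waveform(tab$time_ms, tab$gradient_mT_per_m[-n],
                    delta = meta$delta %||% NA_real_,
                    Delta = meta$Delta %||% NA_real_,
                    T = meta$T %||% NA_real_,
                    m = meta$m %||% NA_real_,
                    G = meta$G %||% NA_real_,
                    label = meta$label %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
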