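---
title: "Modeling flow-compensated IVIM across blood-flow regimes"
author: "flowivim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling flow-compensated IVIM across blood-flow regimes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowivim)
```

## The problem

Intravoxel incoherent motion (IVIM) imaging separates the diffusion-weighted
MR signal into a tissue-water compartment and a microvascular compartment,

$$ S/S_0 = (1-f)\,e^{-bD} + f\,F_P\,e^{-bD_b}, $$

where $f$ is the perfusion fraction, $D$ the tissue diffusivity, $D_b$ the
blood diffusivity (fixed at 1.75 µm²/ms throughout), and $F_P$ the extra
attenuation caused by blood *flow* through the randomly oriented capillary
bed. How $F_P$ depends on the experiment is governed by the ratio of the
diffusion-encoding time $T$ to the time $\tau$ over which blood keeps its
direction of motion:

* **ballistic** regime ($T \ll \tau$): blood moves in straight segments;
  a flow-compensated (FC) waveform with vanishing first gradient moment
  rephases the flowing spins completely;
* **pseudodiffusive** regime ($T \gg \tau$): many direction changes make
  the flow look like diffusion with coefficient
  $D^* = \bar\nu^2\tau/d$; flow compensation has no effect;
* **intermediate** regime ($T \sim \tau$): both $\tau$ and the mean
  squared speed $\bar\nu^2$ shape the signal, and FC gradients achieve a
  *partial* rephasing.

`flowivim` implements a closed-form $F_P$ that covers all three regimes for
a single-refocused double diffusion encoding (DDE) sequence — two bipolar
gradient pairs of lobe duration $\delta$ and separation $\Delta$, with the
encoding time $T$ measured from the start of the first pair to the end of
the second — together with the machinery to derive, validate, simulate and
fit it.

## Flow model and closed form

Blood velocity (the component along the dephasing direction) is modeled as
a Langevin / Ornstein–Uhlenbeck process: relaxation toward zero at rate
$1/\tau$ plus white-noise forcing, which gives a stationary Gaussian
velocity distribution and an exponential velocity autocorrelation
$\langle v(t)v(t')\rangle = \sigma_\nu^2 e^{-|t-t'|/\tau}$ per component.
For isotropic $d$-dimensional flow, $\bar\nu^2 = d\,\sigma_\nu^2$; the
package reports the speed $\nu \equiv \sqrt{\bar\nu^2}$ and uses $d = 3$
by default. The phase accrued against the dephasing factor
$q(t) = \gamma\int_0^t G$ is a linear functional of a Gaussian process and
is therefore exactly Gaussian, so the Gaussian phase approximation
$F_P = \exp(-\langle\varphi^2\rangle/2)$ is exact under the model, with

$$ \langle\varphi^2\rangle
   = \int_0^{T}\!\!\int_0^{T} q(t)\,q(t')\,
     \frac{\bar\nu^2}{d}\,e^{-|t-t'|/\tau}\,dt\,dt'. $$

For the DDE waveform this double integral has the closed form

$$ F_P = \exp\!\Big(-\gamma^2G^2\tfrac{\bar\nu^2\tau}{d}
   \big[\tau^3(\Psi+\Omega) - 4\delta\tau^2 +
        2\delta^2(\Delta-\delta/3)\big]\Big), $$

$$ \Psi = 2e^{-(\Delta+\delta)/\tau}\big(e^{\delta/\tau}-1\big)
          \big(2e^{\Delta/\tau}+e^{\delta/\tau}-1\big), \qquad
   \Omega = m\big(e^{\Delta/\tau}-1\big)^2\big(e^{\delta/\tau}-1\big)^2
            e^{-T/\tau}, $$

with $m=+1$ for non-flow-compensated (NC) and $m=-1$ for FC encoding.
$\Psi$ collects the within-pair correlations (with $\Omega = 0$ the
expression is exactly twice the classic single-bipolar-pair result);
$\Omega$ couples the two pairs across the encoding time and is the only
term distinguishing FC from NC. The frozen forms of $\Psi$ and $\Omega$
were validated against two independent routes:
`phase_variance_analytic()` (exact cell-wise integration for any
piecewise-constant waveform; see below) and `phase_variance_numeric()`
(Gauss–Legendre quadrature); `derive_dde_closed_form()` re-runs that
validation on demand.

```{r closed-form}
p <- ivim_params(f = 0.0475, D = 0.91, v = 1.51, tau = 130)
fp_closed_form(p, G = strength_for_b(200, 8.6, 10),
               delta = 8.6, Delta = 10, T = 50, m = c(1, -1))
```

## The derivation engine

`phase_variance_analytic()` implements the general derivation route: the
integration square $[0,T]^2$ is split by the breakpoints of the
piecewise-linear $q(t)$ and by the diagonal $t=t'$, so that on each cell
the integrand `linear × linear × exponential` has an elementary
antiderivative; the cell contributions are summed in a form whose
exponential arguments are all non-positive (no overflow for short $\tau$)
and rewritten with `expm1` so that no term exceeds the order of $q$ itself
(no cancellation blow-up for long $\tau$). The same algorithm applies to
any waveform built from rectangular gradient lobes — PGSE analogues,
rectangular OGSE — which is the claimed scope; non-piecewise-linear $q$ is
not supported. Expression-level equality with the frozen $\Psi/\Omega$
form is asserted numerically at randomly drawn parameter points
(relative agreement better than $10^{-8}$) rather than by a computer
algebra system.

## Numerical choices

Three pitfalls dominate the numerics, and the package resolves each
without regime switches visible to the user:

* **Short $\tau$**: $e^{\Delta/\tau}$ overflows. $\Psi$ is expanded into
  exponentials with non-positive arguments and $\Omega$ is evaluated in
  log space as
  $m\,e^{-(T-2\Delta-2\delta)/\tau}(1-e^{-\Delta/\tau})^2(1-e^{-\delta/\tau})^2$
  (the DDE constraint $T \ge 2(\Delta+\delta)$ keeps the first factor
  bounded).
* **Long $\tau$**: the bracket suffers catastrophic cancellation between
  $\tau^3\Psi$, $4\delta\tau^2$ and the constant term (the true value
  decays like $1/\tau$ while the terms grow like $\tau^2$). The two
  subtracted terms are exactly the first- and third-order Taylor terms of
  $\tau^3\Psi$ in $1/\tau$, so the bracket is evaluated as
  $\tau^3(\tilde\Psi+\Omega)$ where $\tilde\Psi$ is a sum of fourth-order
  exponential remainders $R_4(z)=e^{-z}-(1-z+z^2/2-z^3/6)$; $R_4$ itself
  switches to its Taylor series below $z=0.5$, where both branches agree
  to better than $10^{-13}$. This reproduces the ballistic limit to
  machine precision without any explicit large-$\tau$ branch.
* **Modulus noise floor** (simulation): the ensemble signal
  $|N^{-1}\sum_j e^{i\varphi_j}|$ is positively biased once the true
  attenuation falls below $\sim(2N)^{-1/2}$, exactly like the Rician floor
  of magnitude MRI. `ensemble_signal()` therefore also returns the mean
  cosine, an unbiased estimator with an exact iid standard error, which is
  what the agreement checks use.

Limit behaviour deserves one honest caveat. The pseudodiffusive reduction
$F_P \to e^{-bD^*}$ is controlled by $\tau$ *against the lobe timing*, not
by $T/\tau$ alone: the $-4\delta\tau^2$ term in the bracket is still 81 %
of the $2\delta^2(\Delta-\delta/3)$ term at $\tau = 5$ ms with the
in-protocol $\delta = 8.6$ ms, and 1 % agreement over the in-protocol
b-grid requires $\tau \lesssim 0.9$ ms. Similarly, the NC ballistic error
scales like (exponent) × $T/\tau$, so sub-percent agreement at $b =
200$ s/mm² needs $T/\tau \lesssim 10^{-3}$. The unit tests assert the
limits at these oracle-derived points. The FC ballistic limit
($F_P \to 1$) is reached to within 0.5 % already at $T/\tau = 10^{-4}$.

## Waveforms and conventions

`make_dde()` stores the *effective* gradient (the refocusing pulse's sign
flip absorbed), so rephasing means a plain zero integral and $q(t)$ never
needs a sign convention mid-sequence. Free time for
$T > 2(\Delta+\delta)$ is placed symmetrically between the pairs, which is
the canonical layout for an encoding-time-parameterized DDE; other
placements would change nothing at the level of $b$, $c$ or the closed
form, because the inter-pair gap enters only through $T$. The first lobe
is stored with negative polarity so that the flow-weighting factor
$c = -\int q\,dt = 2\gamma G\delta\Delta$ comes out nonnegative for NC;
only $c^2$ is ever used. Lobes are ideal rectangles; slew-rate-limited
trapezoids are out of scope.

## The Langevin simulator

`simulate_phases()` draws initial velocities from the stationary
distribution (no burn-in needed), advances them with the Euler–Maruyama
update $v \leftarrow v(1-\Delta t/\tau) + \sqrt{2\sigma_\nu^2\Delta
t/\tau}\,\xi$, and accrues phases with $q$ integrated exactly over each
step. The default $\Delta t = 0.1$ ms keeps the discretization bias of
the stationary variance at $\Delta t/(2\tau) \le 0.5\,\%$ for
$\tau \ge 10$ ms; if $\Delta t > \tau/20$ the step is refined
automatically with a warning. One velocity component is simulated — for
linear encoding the phase depends only on the projection onto the
dephasing direction — and a list of waveforms sharing the encoding
interval reuses identical trajectories, which makes FC/NC comparisons on
the same ensemble exact. Monte-Carlo standard errors come from a 20-fold
walker jackknife (modulus) or the iid formula (mean cosine).

```{r simulator}
w_nc <- make_dde(strength_for_b(100, 8.6, 10), 8.6, 10, T = 50)
e <- simulate_phases(w_nc, tau = 200, sigma_v = 1.5,
                     n_walkers = 5000, seed = 1)
ensemble_signal(e)[, c("fp_cos", "se_cos")]
p_flow <- ivim_params(f = 1, D = 0, v = sqrt(3) * 1.5, tau = 200)
fp_closed_form(p_flow, strength_for_b(100, 8.6, 10), 8.6, 10, 50, 1)
```

## Synthetic data

`default_protocol()` reproduces the emulated brain acquisition: $b$ = 0,
5, 10, 20, 30, 100, 200 s/mm², $T$ = 50, 60, 85, 100 ms, FC and NC
($7 \times 4 \times 2 = 56$ samples per voxel), $\delta = 8.6$ ms,
$\Delta = 10$ ms, six encoding directions combined by geometric
averaging. Rician noise is applied at $\sigma = S_0/\mathrm{SNR}$ *after*
direction averaging (the quoted SNR of 30–70 for brain already folds in
the averaging); a per-direction slow path (`add_rician_directions()`) is
available. The brain-like defaults $f = 4.75\,\%$, $D = 0.91$ µm²/ms,
$\nu = 1.51$ mm/s with $\tau$ = 10 / 130 / 800 ms for the diffusive /
intermediate / ballistic regimes are typical healthy-brain values and are
the fixed study conditions for the recovery experiments.

What the generator emulates is the *signal model plus magnitude noise*;
it deliberately omits EPI distortion and drift, partial-volume mixing,
hematocrit-dependent $D_b$, non-Gaussian tissue diffusion and anisotropy.
Passing recovery tests therefore demonstrates correctness of model,
noise and estimator — not robustness to those real-world effects.

## Bayesian fitting

`fit_voxel()` samples the posterior of $(D, f, \nu, \tau, S_0)$ under the
uniform priors $D\in[0,3]$ µm²/ms, $f\in[0,1]$, $\nu\in[0,5]$ mm/s,
$\tau\in[1,1000]$ ms, $S_0\in[0,2\max S]$, with $D_b$ fixed. The
magnitude-Gaussian likelihood's noise SD is marginalized analytically
under a Jeffreys prior (posterior $\propto \mathrm{RSS}^{-n/2}$) — the
same marginal posterior as sampling the SD explicitly, with one fewer
dimension; a fixed-SD Gaussian is available via `noise_sd` (at the SNRs
of interest, $\ge 20$, the Rician and Gaussian likelihoods are
indistinguishable). $\tau$ is proposed on the log scale (its prior spans
three decades) with the Jacobian keeping the prior uniform in $\tau$;
out-of-bounds proposals are rejected. The sampler combines componentwise
random-walk Metropolis (scales adapted toward 44 % acceptance during
burn-in) with one joint proposal per sweep drawn from the adapted
empirical covariance: the $(f,\nu,\tau)$ posterior forms a curved ridge —
small $\nu$ with large $f$ mimics large $\nu$ with small $f$ — that
componentwise moves traverse very slowly. Convergence is monitored by
split-$\hat R$ and flagged above 1.05. Fitting is voxel-wise independent
throughout; no spatial prior is used.

At high SNR the posterior medians recover the generating values to a few
per mil. At realistic brain SNR (≈50) the perfusion parameters are only
weakly identified and the uniform priors pull the voxel-wise posterior
medians: $f$ is overestimated by several percentage points, $\nu$
underestimated, and $\tau$ biased away from its true value (up in the
diffusive/intermediate regimes, down — against the prior ceiling — in
the ballistic regime). These directions are intrinsic to bounded uniform
priors under weak identifiability. Their magnitudes are substantially
smaller when fitting is regularized spatially across voxels — pooling
information that voxel-wise fitting by construction cannot use — so maps
produced by spatially-regularized pipelines are not directly comparable
with the voxel-wise bias figures quantified here by `snr_sweep()`.

## Desk-scale experiment sizes

The scripted experiments use deliberately modest sizes chosen to give
stable medians: the analytic-vs-simulation curves use the full $N =
20\,000$ walkers at $\Delta t = 0.1$ ms; the convergence scan a
$T/\tau$ grid of step 0.05; the recovery study 100 voxels per condition
with 20 000 retained draws after 10 000 burn-in (tests use shorter
chains, which is enough for sign and direction checks), at SNR levels
{20, 50, 200, 2000} rather than a continuous sweep.

## Known limitations

* The closed form assumes the exponential VACF; a linear VACF (straight
  equal-length segments) is supported only by the numerical engine, and
  is in any case incompatible with the Gaussian phase approximation.
* Voxel-wise fitting at brain-like perfusion and SNR carries substantial
  prior-driven bias (above); interpret absolute $f$, $\nu$, $\tau$ maps
  at low SNR with care.
* $\tau$ estimates saturating near the 1000 ms prior bound indicate an
  effectively ballistic voxel, not a measured correlation time.
* Tensor-valued encoding, trapezoidal lobes, imaging/crusher gradients,
  and explicit capillary-network geometry are out of scope.
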