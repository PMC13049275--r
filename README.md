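# flowivim

Encoding-time-dependent, flow-compensated intravoxel incoherent motion
(IVIM) modeling for diffusion MRI.

Classical IVIM analysis assumes microvascular blood flow behaves like
pseudodiffusion, which is only true when the diffusion-encoding time *T*
is much longer than the blood velocity correlation time τ. At clinical
encoding times in brain, *T* and τ are comparable, and the perfusion
signal depends on both the blood speed ν and τ. `flowivim` implements a
closed-form perfusion attenuation for a flow-compensated /
non-flow-compensated (FC/NC) double diffusion encoding (DDE) sequence
that spans the ballistic, intermediate and pseudodiffusive regimes, and
everything needed to work with it: waveform algebra, a phase-variance
derivation engine for arbitrary rectangular-lobe waveforms, a Langevin
Monte-Carlo simulator, synthetic data generation, and voxel-wise Bayesian
parameter mapping. It is aimed at diffusion-MRI methods researchers who
want to model, simulate or fit multi-encoding-time FC/NC IVIM data.

## The model

Blood velocity is modeled as an Ornstein–Uhlenbeck (Langevin) process
with exponential velocity autocorrelation
⟨v(t)v(t′)⟩ = (ν̄²/d)·exp(−|t−t′|/τ). Under the (here exact) Gaussian
phase approximation, the perfusion attenuation for a DDE waveform with
lobe duration δ, lobe separation Δ, amplitude G and encoding time T is

    F_P = exp( −γ²G² (ν̄²τ/d) [ τ³(Ψ+Ω) − 4δτ² + 2δ²(Δ−δ/3) ] )

    Ψ = 2 e^{−(Δ+δ)/τ} (e^{δ/τ}−1) (2e^{Δ/τ} + e^{δ/τ} − 1)
    Ω = m (e^{Δ/τ}−1)² (e^{δ/τ}−1)² e^{−T/τ},   m = +1 (NC), −1 (FC)

which plugs into the two-compartment IVIM signal
S = S₀[(1−f)e^{−bD} + f·F_P·e^{−bD_b}]. For τ → 0 this reduces to the
pseudodiffusion model exp(−bD*) with D* = ν̄²τ/d; for τ → ∞ it reduces
to the ballistic model exp(−c²ν̄²/2d) (NC) and 1 (FC), with
c = −∫q(t)dt the flow-weighting factor.

## Worked example

```r
library(flowivim)

# a DDE waveform at b = 200 s/mm2 with the in-vivo timing
G <- strength_for_b(200, delta = 8.6, Delta = 10)   # 51.46 mT/m
w <- make_dde(G, 8.6, 10, T = 50)
bvalue(w)   # 200 (s/mm2)
cvalue(w)   # 2.368 (s/mm)

# closed-form perfusion attenuation, brain-like microvasculature
p <- ivim_params(f = 0.0475, D = 0.91, v = 1.51, tau = 130)
fp_closed_form(p, G, 8.6, 10, T = 50, m = c(1, -1))
#> 0.1543962 0.8243818
```

At b = 200 s/mm², T = 50 ms, a blood pool with ν = 1.51 mm/s and
τ = 130 ms keeps only 15 % of its signal under NC encoding but 82 % under
FC encoding — the intermediate-regime rephasing that multi-*T* FC/NC
acquisitions exploit. The full forward signal for the emulated brain
protocol (56 samples: b = 0–200 s/mm², T = 50–100 ms, FC and NC) and a
Bayesian fit of one noisy synthetic voxel:

```r
pro <- default_protocol()
s   <- ivim_signal(p, pro)
s[pro$b == 100 & pro$T == 50]       # NC 0.88532, FC 0.90585

dat <- add_rician(noisefree_dataset(p, pro), snr = 50, seed = 7)
fit <- fit_voxel(dat, pro, n_samples = 4000, burn_in = 2000, seed = 1)
coef(fit)["D"]    # 0.789 um2/ms (truth 0.91)
```

The fit returns per-parameter posterior medians, 95 % intervals and
split-R̂. Note the wide intervals (e.g. f: 0.03–0.55 for a true 0.0475):
at SNR = 50 the perfusion parameters of a single brain-like voxel are
weakly identified, and voxel-wise posterior medians carry substantial
prior-driven bias — quantified by `snr_sweep()` and discussed in the
vignette (`vignettes/flow-compensated-ivim.Rmd`).

Monte-Carlo validation and the regime scan:

```r
e <- simulate_phases(w, tau = 200, sigma_v = 1.5, n_walkers = 20000,
                     dt = 0.1, seed = 1)
ensemble_signal(e)                  # simulated F_P with Monte-Carlo SE

regime_convergence_scan()$convergence_point   # T/tau = 5: FC and NC merge
```

A thin CLI over these functions (subcommands `predict`, `derive`,
`simulate`, `fit`) is installed at `inst/cli/flowivim`.

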