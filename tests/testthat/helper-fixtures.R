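# Shared fixtures: the in-vivo-style timing and a reduced protocol for
# fast inference tests.

DELTA <- 8.6   # lobe duration [ms]
DDELTA <- 10   # lobe separation [ms]

# brain-like generating parameters
brain_params <- function(tau = 130) {
  ivim_params(f = 0.0475, D = 0.91, v = 1.51, tau = tau, S0 = 1)
}

# protocol with fewer b-values/encoding times, for fast MCMC tests
quick_protocol <- function() {
  default_protocol(b = c(0, 5, 20, 100, 200), T_ms = c(50, 100))
}

# relative error helper
rel_err <- function(x, ref) abs(x - ref) / abs(ref)

# waveform grid used by several property tests (all satisfy delta <= Delta
# and T >= 2*(Delta+delta))
waveform_grid <- expand.grid(delta = c(4, 7, 10), Delta = c(10, 12, 14),
                             T = c(50, 60, 85, 100), m = c(1, -1))
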