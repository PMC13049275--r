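Package: flowivim
Title: Encoding-Time-Dependent Flow-Compensated IVIM Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical and Monte-Carlo tools for intravoxel incoherent motion
    (IVIM) MRI with flow-compensated and non-flow-compensated double diffusion
    encoding (FC/NC DDE). Represents piecewise-constant diffusion-encoding
    gradient waveforms and their dephasing factor, b-value and flow-weighting
    c-value; evaluates a closed-form perfusion attenuation built from an
    exponentially correlated (Langevin) blood velocity model, together with its
    diffusive and ballistic limiting cases; derives phase variances for
    arbitrary piecewise waveforms by exact integration and by numerical
    quadrature; simulates blood flow with a discrete Langevin update to form
    ensemble signals; generates synthetic multi-encoding-time FC/NC datasets
    with Rician noise; and estimates microvascular parameters (perfusion
    fraction, tissue diffusivity, blood velocity and velocity correlation time)
    by voxel-wise Bayesian MCMC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils,
    yaml,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
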