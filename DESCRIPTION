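Package: rrochaos
Title: Chaotic and Stochastic Resonance in a Discrete Excitatory-Inhibitory
    Neural Map with Reduced-Region-of-Orbit Feedback
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates the Sinha discrete neural system of coupled excitatory
    and inhibitory neurons in its reduced one-dimensional form, a
    piecewise-linear map of the effective neural potential.  Provides the
    reduced-region-of-orbit (RRO) feedback term with positive or negative
    strength, additive Gaussian noise, and a weak sinusoidal drive; the
    analytic attractor-merging condition with bisection solvers for critical
    parameter values; trajectory simulation with binarization; the
    occurrence probability of chaos-chaos intermittency; the delay-maximized
    signal-response correlation; and Lyapunov exponent estimation by orbit
    perturbation.  Parameter sweep drivers reproduce bifurcation scans,
    resonance curves, and two-dimensional response surfaces for comparing
    chaotic resonance induced by negative RRO feedback with stochastic
    resonance induced by noise.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
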