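Package: sirsTuring
Title: Turing Instability and Pattern Formation in a Stochastic Spatial
    SIRS Model with Reinfection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing diffusion- and noise-driven (Turing-type)
    instabilities in a spatiotemporal SIRS epidemic model with saturated
    incidence and reinfection.  Provides the reaction kinetics and endemic
    equilibria of the model, a second-order (moment-closure) stochastic
    stability analysis built on a 9x9 moment-evolution matrix, dispersion
    curves, Turing-threshold and stability-region computation, an explicit
    Euler-Maruyama integrator for the 2D stochastic reaction-diffusion
    system with no-flux boundaries, and diagnostics (grid-convergence
    studies, dominant pattern wavenumber) that link simulated patterns back
    to the linear and second-order analyses.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
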