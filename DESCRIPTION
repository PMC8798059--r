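Package: mtkinetics
Title: Microtubule Dynamic Instability Simulation and Kymograph Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying microtubule dynamic instability from
    fluorescence microscopy assays and for validating those measurements
    against a stochastic generative model. Includes a dynamic-instability
    simulator (growth, catastrophe, templated and spontaneous nucleation,
    stabilized-seed depolymerization), a synthetic TIRF kymograph and
    field-of-view renderer with a Gaussian point-spread function and
    Poisson shot noise, automated kymograph tip tracking with penalized
    change-point phase segmentation, and the statistical layer used to
    characterize microtubule assembly factors: linear growth-kinetics
    regression yielding apparent on-rate, off-rate and critical
    concentration, endpoint-constrained Hill fits of templated nucleation
    probability, linear fits of spontaneous nucleation counts, catastrophe
    frequencies with bootstrap confidence intervals, censored
    nucleation-lag distributions, intensity line profiles and
    curvature-intensity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    survival,
    minpack.lm,
    igraph,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
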