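Package: flvisc
Title: Core-Annulus Modeling of the Fahraeus-Lindqvist Effect
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuum-mechanics core-annulus model of the Fahraeus-Lindqvist
    effect in small blood vessels. Computes the asymptotic core radius,
    cell-poor marginal layer thickness, two-region axial velocity profile and
    apparent relative viscosity of blood flowing in a cylindrical tube, given
    the tube diameter, the red-blood-cell exclusion half-thickness, the
    marginal viscosity fraction and the core relative viscosity (or the
    discharge hematocrit via the Charm-Kurland correlation). Evaluates the
    classical Charm-Kurland, Pries and Secomb empirical viscosity laws, fits
    the three model parameters to viscosity-diameter datasets by bounded
    nonlinear least squares with a deterministic multistart, and generates
    synthetic viscosity-diameter series with multiplicative relative noise
    for parameter-recovery studies. Includes a command-line interface for
    prediction, curve generation, law comparison, fitting and simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    minpack.lm,
    optparse,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
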