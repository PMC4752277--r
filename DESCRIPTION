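Package: phagegut
Title: Temperate Phage-Bacteria Population Dynamics in the Mouse Gut
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic five-population model of temperate bacteriophage
    lambda and Escherichia coli in the monoxenic mouse gastrointestinal
    tract: susceptible bacteria, resident and newly formed lysogens, latent
    (lytically committed) cells and free phage, coupled through logistic
    growth, adsorption, the lysis-lysogeny decision, prophage induction and
    intestinal washout. Provides the ODE core (simulation, two-phase regime
    switches, equilibrium analysis), a sequential nonlinear least-squares
    calibration pipeline with case-bootstrap confidence intervals,
    closed-form estimators for plate-assay quantities (adsorption rate,
    burst size, induction rate), one-at-a-time parameter sensitivity
    sweeps, and a synthetic fecal time-series generator emulating
    gnotobiotic mouse competition experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
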