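Package: iftdyn
Title: Simulation and Analysis of Intraflagellar Transport Dynamics at the Ciliary Tip
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Stochastic simulation and quantitative analysis of intraflagellar
    transport (IFT) turnaround at the flagellar tip. Generates synthetic train
    schedules, single-particle trajectories, kymographs, spot image stacks and
    FRAP series with realistic photophysics; localizes spots by 2D Gaussian
    fitting and extracts velocities, lateral fluctuations and MSD-based
    diffusion coefficients; fits Gamma dwell-time and linear tip-remodeling
    models to tip resting times; runs a fluorophore-counting Monte Carlo of
    photogated train mixing; fits 1D diffusion models to FRAP recoveries and
    balances diffusive efflux against IFT influx by Fick's law; and simulates
    the steady-state diffusive return of kinesin-II from tip to base,
    including mean first-passage times and the accumulation relative to a
    hypothetical active-return scenario.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    minpack.lm,
    jsonlite,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
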