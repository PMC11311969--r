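Package: laurdanscope
Title: Membrane-Phase and Photophysics Analysis of Laurdan in Lipid Bilayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory analysis and fluorescence observables for the
    solvatochromic membrane probe Laurdan embedded in a DPPC bilayer across
    the liquid-crystal, gel, ripple and liquid-disordered phases. Computes
    probe orientation and depth statistics, water radial distribution
    functions, hydrogen-bond counts and post-excitation solvent-orientation
    relaxation, membrane-phase fingerprints (area per lipid, deuterium order
    parameters, two-dimensional thickness maps with ripple metrics), and
    optical observables: Gaussian-broadened emission spectra, generalized
    polarization, radiative lifetimes, anisotropy decay from the transition
    dipole autocorrelation, TCSPC decay simulation and Poisson
    maximum-likelihood multi-exponential lifetime fitting with instrument
    response reconvolution, two-population anisotropy mixtures and
    steady-state anisotropy. A synthetic-data module generates bilayer, probe
    and water trajectories and emission tables with known ground truth so the
    whole pipeline runs without a molecular-dynamics engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
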