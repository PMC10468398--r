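Package: iondrop
Title: Droplet Ionic Power Sources and Calcium-Wave Imaging Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models a microscale soft ionic power source built from five
    salt-gradient hydrogel droplets (reverse electrodialysis between
    ion-selective compartments) and quantifies its effect on neuronal
    network activity in calcium-imaging recordings. Provides an analytic
    equivalent-circuit model (electromotive force, internal resistance,
    load sweeps, series/parallel composition, charge budget, power
    density), a transient 1-D finite-volume Nernst-Planck solver with
    algebraic electroneutrality for open-circuit, short-circuit,
    resistive-load and recharge modes, imaging statistics (relative
    concentration, weighted-mean centre of fluorescence, relative
    displacement, wave speed, activation-pattern classification, group
    comparison), and seeded synthetic generators for discharge traces and
    time-lapse fluorescence stacks with planted ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
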