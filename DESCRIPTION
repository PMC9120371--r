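Package: spindleloop
Title: Thalamocortical Neural Mass Modelling of Sleep Spindles and Slow
    Oscillations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates a hybrid thalamocortical neural mass model of NREM
    sleep in which a conductance-based thalamic node (thalamocortical relay
    and reticular populations with T-type calcium, potassium-leak and
    hyperpolarization-activated currents) generates waxing-and-waning sleep
    spindles, and a mean-field model of adaptive exponential
    integrate-and-fire neurons generates cortical slow oscillations with UP
    and DOWN states. The two nodes are coupled by delayed firing rates into
    a closed thalamocortical loop. Ships forward-Euler integrators with
    Ornstein-Uhlenbeck background drive, precomputation of the
    Fokker-Planck steady-state transfer functions of the cortical
    population, an A7-style sigma-band spindle detector, cross-frequency
    coupling statistics (Kullback-Leibler modulation index, mean vector
    length, phase-locking value, mutual information on equiquantal bins)
    with iterative amplitude-adjusted Fourier-transform surrogate
    significance testing, and parameter-sweep and event-locked analysis
    utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
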