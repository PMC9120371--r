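# spindleloop

Simulation and analysis of a hybrid thalamocortical neural mass model of
NREM sleep. A conductance-based thalamic node (thalamocortical relay +
reticular populations with potassium-leak, T-type calcium and
hyperpolarization-activated currents) generates waxing-and-waning sleep
spindles in the 12–15 Hz sigma band; a mean-field model of adaptive
exponential integrate-and-fire (AdEx) populations generates the cortical
slow oscillation (~1 Hz UP/DOWN alternation). The two nodes are coupled by
their firing rates with a 13 ms delay in both directions, and the package
ships the full analysis stack used to study their interaction:

* forward-Euler integrators (dt = 0.01 ms) with pre-integrated
  Ornstein–Uhlenbeck background drive and exact delay buffers, in compiled
  code;
* precomputation of the cortical transfer functions
  Φ<sub>r</sub>, Φ<sub>V</sub>, Φ<sub>τ</sub>(μ, σ) by stationary
  Fokker–Planck threshold integration, validated against a Monte-Carlo
  simulation of independent AdEx neurons;
* an A7-style sigma-band spindle detector adapted to model rate series;
* cross-frequency coupling statistics between slow-oscillation phase and
  spindle amplitude/phase — Kullback–Leibler modulation index, mean vector
  length, phase-locking value, mutual information on equal-occupancy bins —
  with IAAFT surrogate significance testing;
* parameter sweeps, DOWN-state detection, event-locked averages, circular
  phase statistics, and synthetic fixture generators with known ground
  truth.

The model's core phenomenology: the isolated thalamus spindles
spontaneously in two disjoint conductance regions with a ~13 Hz carrier;
the isolated cortex moves through DOWN fixed point, fast E-I limit cycle,
adaptation-driven slow limit cycle and UP fixed point as its background
currents vary; in the coupled loop with a predominantly UP cortex, each
noise-induced cortical DOWN state opens a window of opportunity for a
thalamic spindle, which is imprinted back onto the following UP state —
yielding significant phase-amplitude coupling between slow-oscillation
phase and spindle amplitude with a preferred phase just after the UP-state
onset, and no phase-phase coupling.

## Worked example

```r
library(spindleloop)

## spontaneously spindling thalamic node, 65 s
sim <- simulate_thalamus(thalamic_params(), sim_grid(65e3, seed = 1))
post <- drop_transient(sim)          # discard the first 5 s
ev <- detect_spindles(post)
nrow(ev)                             # 25 spindles in 60 s
mean(ev$duration)                    # 0.69 s mean duration
mean(ev$mean_frequency)              # 13.5 Hz carrier
dominant_frequency(post$r_TCR, 100, band = c(10, 20))  # 13.5 Hz

## coupled loop in the short-UP-state regime, 125 s
loop <- simulate_loop(
  cortical_params(mu_E = 0.61, mu_I = 0.4, sigma_E = 0.05, sigma_I = 0.05),
  thalamic_params(g_LK = 0.033), loop_config(N_ctx_thal = 1.2,
                                             N_thal_ctx = 0.12),
  sim_grid(125e3, seed = 1), ou_tcr = ou_params(sigma = 0.005))
x <- drop_transient(loop)
suite <- cfc_suite(x$r_E, x$r_TCR, fs = 100, n_surr = 999, seed = 1)
suite$klmi   # KL-MI = 0.0012, p = 0.001  (phase-amplitude: coupled)
suite$plv    # PLV  = 0.0018, p = 0.27    (phase-phase: not coupled)
Arg(suite$mvl$raw)  # 0.56 rad: spindles peak just after the SO phase 0
```

The first `simulate_cortex()`/`simulate_loop()` call builds the cortical
transfer table (~20 s) and caches it for the session; pass `table =` to
reuse one across scripts.

A thin command-line front end is installed at
`system.file("cli/spindleloop", package = "spindleloop")` with subcommands
`simulate`, `detect`, `cfc`, `sweep-thalamus`, `sweep-cortex`,
`sweep-loop`, `make-fixture`.

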