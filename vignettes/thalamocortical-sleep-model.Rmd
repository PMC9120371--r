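---
title: "A hybrid thalamocortical mass model of NREM sleep rhythms: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid thalamocortical mass model of NREM sleep rhythms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`spindleloop` simulates a two-node neural mass model of the sleeping
thalamocortical system. The thalamic node generates fast sleep spindles
(sigma band, 12–15 Hz) with a waxing-and-waning envelope; the cortical node
generates the ~1 Hz slow oscillation with its alternation of active (UP)
and silent (DOWN) states. Coupled by their firing rates with a 13 ms
conduction delay in both directions, the two nodes reproduce the
characteristic nesting of spindles into the cortical slow oscillation
during deep NREM sleep.

## Thalamic node

Two populations — the excitatory thalamocortical relay (TCR) and the
inhibitory reticular nucleus (TRN) — are described by their mean membrane
potentials. A sigmoidal transfer function (maximum 400 Hz, threshold
−58.5 mV, gain 6 mV with a logistic gain factor of $\pi/\sqrt{3}$) converts
potential to population rate. Synapses are conductance-based with
alpha-kernel responses, implemented as critically damped second-order ODEs
(AMPA decay 70 s⁻¹, GABA\(_A\) decay 100 s⁻¹); intra-thalamic connectivity
is TRN→TCR = 5, TCR→TRN = 3, TRN→TRN = 25 (relay cells make no local
collaterals).

Spindling rests on three intrinsic currents. A potassium leak current
(conductance `g_LK`) sets the tonic hyperpolarization level. A low-threshold
T-type calcium current (instantaneous activation $m_\infty^2$, slow
inactivation gate $h$) de-inactivates under hyperpolarization and produces
rebound bursts; the TRN acts as the pacemaker, periodically inhibiting the
TCR whose rebound re-excites the TRN at ~13 Hz. The relay population
additionally carries the anomalous rectifier $I_h$ with a two-state open
mechanism: calcium entering through the T current binds a regulating factor
that locks $I_h$ open with doubled conductance, depolarizing the TCR until
rebound bursting fails — this slow negative feedback terminates each spindle
and produces the waxing-and-waning envelope. The gating kinetics
(relay T current after Destexhe et al. 1998, reticular T current and the
calcium-dependent $I_h$ scheme after Destexhe et al. 1996) and all default
constants follow the published conductance-based thalamic mass model they
were assembled into (Schellenberger Costa et al. 2016); they are collected
in `thalamic_params()` with per-value comments.

Depending on `g_LK` and `g_h` the isolated node shows two disjoint regions
of spontaneous waxing-and-waning spindling (around `g_LK` ≈ 0.018 and
0.031 mS/cm²), a continuous (non-waxing) sigma oscillation between them
(noise there *induces* waxing-and-waning), constant-rate fixed points in
the conductance corners, and a monotone dependence of the spindle carrier
frequency on the relay T-current conductance across the 12–15 Hz band.

## Cortical node

The cortical node is a mean-field reduction of two delay-coupled
populations of adaptive exponential integrate-and-fire (AdEx) neurons
(excitatory with somatic spike-frequency adaptation, inhibitory without).
The reduction is a linear-nonlinear cascade: for stationary white-noise
input with mean $\mu$ and standard deviation $\sigma$, the population rate,
mean membrane voltage and an effective low-pass timescale are given by
precomputed transfer functions $\Phi_r, \Phi_V, \Phi_\tau(\mu, \sigma)$.
The state variables are the mean membrane currents of both populations, the
mean adaptation current (subtracted from the excitatory lookup input as
$\mu_E - \bar I_A / C$), and the means and variances of the fractions of
active synapses per channel, whose input terms are the dimensionless
delayed-rate products $c\,K\,\tau_s\,r(t-d)$ (this dimensionless form is
the only reading under which the variance equations are dimensionally
consistent). The input variance $\sigma_\alpha^2$ combines the synaptic
variance contributions with a constant external part. External drive is an
Ornstein-Uhlenbeck current per population (relaxation time 5 ms), whose
drifts are the principal control parameters, quoted in nA (divide by the
membrane capacitance, 200 pF, for mV/ms).

### Transfer-table computation

`build_transfer_table()` computes the stationary Fokker-Planck solution of
the exponential integrate-and-fire neuron by backward threshold integration
on a voltage grid (default −200 mV to the threshold at 0.05 mV steps, a
locally exact exponential stepper, overflow-safe rescaling deep below
threshold). The rate follows from normalization, the mean voltage includes
the refractory occupation at the reset. The effective timescale is obtained
from the linear rate response to mean-input modulation (backward integration
of the perturbed density/flux pair at eight frequencies between 1 and
200 Hz) by a least-squares fit of a one-pole low-pass kernel — the
"exponential link" reduction. Tables default to 201 × 21 grid points over
$\mu \in [-2, 8]$ mV/ms, $\sigma \in [0.05, 5.05]$ mV/ms^1.5 — chosen so a
table builds in well under a minute while bilinear interpolation error
stays far below the Monte-Carlo validation tolerance; lookups are bilinear
with clamped extrapolation. `mc_eif_rate()` provides the brute-force
validation oracle (independent AdEx neurons under matching noise); the test
suite requires agreement within 5%, and the observed discrepancy is a few
tenths of a percent.

### Parameter provenance and the calibrated constants

Single-neuron, synaptic and connectivity constants are the published values
of the cascade model of AdEx populations (Augustin et al. 2017; Cakan &
Obermayer 2020): C = 200 pF, gL = 10 nS, EL = −65 mV, ΔT = 1.5 mV,
VT = −50 mV, Vr = −70 mV, Vs = −40 mV, Tref = 1.5 ms; J's of 2.43, 2.60,
−3.3, −1.64 mV/ms; increments 0.3/0.5; in-degrees 800/200; synaptic decays
2/5 ms; delays 4/2 ms. Four constants of the population setup are not fixed
by those sources and were chosen, once, so that the node reproduces the
canonical NREM state space of the hybrid model — a DOWN fixed point at weak
excitatory drive, an adaptation-driven slow (≤ 2 Hz) limit cycle around
$\mu_E = 0.56$ nA at $\mu_I = 0.4$ nA, UP states with noise-induced DOWN
excursions at $\mu_E = 0.61$–0.7 nA, and a fast E-I limit cycle at weak
inhibitory drive: spike-triggered adaptation b = 50 pA with timescale
400 ms (no subthreshold adaptation), and external variance contributions of
1.5 (E) and 1.0 (I) mV/ms^1.5. Two residual misfits of this calibration are
documented rather than hidden: the slow-cycle window starts near 0.53 nA
(instead of extending down to ~0.47), and the E-I cycle's dominant
frequency is ~21–22 Hz rather than ~25 Hz.

## The loop and its unit bridging

Rates cross the node interface in kHz. The cortical excitatory rate enters
the AMPA input of both thalamic populations as
$N_{ctx\to thal}\, r_E(t-13\,\mathrm{ms})$; the relay rate enters the
cortical excitatory synaptic channel as
$N_{thal\to ctx}\, r_{TCR}(t-13\,\mathrm{ms})$ through a dedicated
long-range afferent channel with its own increment constant and in-degree
(`c_ext` = 0.25, `K_ext` = 250). Realistic coupling strengths are unknown
(the two directions are expected to differ roughly ten-fold, matching the
~ten-fold difference in peak rates), so the `N` values are free parameters;
`c_ext` was fixed so that the documented strong-coupling parametrization
(N 1.2 / 0.12) produces the intended regime: cortical UP states with
irregular DOWN windows, each DOWN window opening an opportunity for a
thalamic spindle which is then imprinted onto the following UP state. In
the DOWN-dominant cortical regime the causality reverses: free thalamic
spindles drive DOWN→UP transitions.

# Numerics

Forward Euler with dt = 0.01 ms; all outputs subsampled at 10 ms, fixing
the analysis rate at 100 Hz. Background noise is pre-integrated
Ornstein-Uhlenbeck at dt resolution and inserted with zero-order hold. One
master seed derives fixed-order sub-streams (TCR, E, I), so switching a
noise source on or off never alters another source's stream; noise-free
runs are bit-reproducible and seed-independent. Delay buffers hold exactly
`round(delay/dt)` steps (13 ms ↔ 1300 steps) and are pre-filled with the
initial state so nodes at a fixed point stay there. Initial conditions:
thalamic voltages at the leak reversal with gates at their steady states;
cortical mean currents at their drifts with synapses empty. The first 5 s
of every statistic-producing run are discarded. Halving dt changes a 5 s
thalamic trajectory by under 1% RMS (tested). Divergence (non-finite
state) is reported with the time of first failure; sweep points that
diverge are recorded as missing rather than failing the sweep.

# Spindle detection

`detect_spindles()` is a sigma-band detector in the style of the A7
algorithm, adapted to model rate series (which, unlike EEG, have no
broadband background). Three decision streams are computed on the z-scored
signal: relative sigma power (2 s windows, 200 ms steps), the moving
correlation between the sigma-filtered and broadband (1–30 Hz) signals, and
the moving RMS of the sigma-filtered signal (both 300 ms windows, 100 ms
steps; RMS threshold at mean + 1.5 SD). A sample is spindle-candidate when
all three streams pass threshold — the conjunctive rule of the original
algorithm; on model output the two spectral streams saturate (the whole
signal is sigma-dominated) and the envelope stream carries the
discrimination, while on noisy signals the correlation stream suppresses
chance sigma-power fluctuations. Candidate cores shorter than half the
minimum duration are discarded, neighbours within 500 ms merged, and each
event is refined on the Hilbert sigma envelope: its boundaries are the
crossings of max(soft envelope threshold, half the event's own peak), so
the reported duration is the width of the waxing-and-waning envelope at the
detection level. Durations are resolution-limited by the 3 Hz analysis
band (~0.3 s envelope impulse width): bursts much shorter than that are
reported near the resolution limit. Two thresholds are relaxed for
model/cortical signals exactly as in the source study (minimum duration
0.5 → 0.3 s, relative power 0.2 → 0.15; `preset = "cortical"`); everything
else keeps the published defaults (correlation 0.65, RMS 1.5 SD, maximum
duration 2.5 s).

# Cross-frequency coupling

Band-limited phase and amplitude come from a zero-phase (one-pass,
group-delay-compensated) Hamming FIR bandpass followed by the Hilbert
transform; bands are 0.1–3 Hz (slow oscillation) and 12–15 Hz (fast
spindles). Four statistics are provided: the Kullback-Leibler modulation
index (18 phase bins by default; the bin count is a free choice and is
exposed), the mean vector length, the phase-locking value and the mutual
information between phase series on 16 equal-occupancy bins. MVL and PLV
are implemented as *time averages* (divided by the sample count) — sum
normalization would make the values length-dependent; user-facing note:
reported MVL magnitudes therefore scale with the spindle amplitude in the
signal's units (Hz here).

Significance testing uses iterative amplitude-adjusted Fourier-transform
surrogates, which preserve the value distribution exactly and the power
spectrum to within the iteration tolerance (stop after 200 iterations, on
a spectral change below 1e-8, or when the rank ordering reaches a fixed
point). The surrogate scheme: the spindle-carrying signal is surrogated,
the slow-oscillation phase series is held fixed, and filtering, Hilbert
transform and statistic are recomputed per surrogate — this tests the
coupling null while preserving both marginals. Empirical p-values follow
the `(1 + k)/(1 + n)` rule, one-sided (greater). `cfc_suite()` computes all
four statistics against a single shared surrogate set.

# Synthetic fixtures

`generate_pac_signal()` produces a slow cosine plus a fast sine whose
envelope is modulated by the slow phase with known depth and preferred
phase (the cosine convention makes the Hilbert phase at the amplitude
maximum equal the nominal preferred phase); `generate_spindle_train()`
produces Gaussian-envelope sigma bursts on white noise with stored ground
truth. These fixtures emulate the *spectral* structure the analysis stack
must resolve — they do not emulate the asymmetric, non-sinusoidal waveforms,
rate floors at zero, or state-dependent noise of real model output (let
alone EEG), so detector and coupling tests passing on fixtures demonstrate
correct signal processing, not physiological validity.

# Problem sizes

Defaults used by the tests and the acceptance analysis: 20 s runs for
fixed points, 65 s for spindle statistics (5 s discarded), 30 s for
cortical regime probes, 125 s for the coupled-loop coupling analysis,
transfer tables of 201 × 21 points, sweeps on coarse grids (≤ 15 × 15; the
sweep API takes arbitrary axes for full-resolution maps), and up to 1000
surrogates for the significance tests.

# Known limitations

* The DOWN-corner fixed point of the thalamic node (g_LK = g_h =
  0.08 mS/cm²) settles at ~5.6 Hz with the adopted kinetics; systematic
  variation of every unprinted constant showed that raising it towards
  10 Hz destroys the spindling landscape, so the discrepancy is retained
  (all other thalamic landmarks, including the opposite corner at
  ~116 Hz, reproduce).
* Cortical slow-cycle window and E-I cycle frequency are slightly offset
  (see calibration notes above); cortical DOWN states in the coupled loop
  are shorter than in the reference dynamics, which lowers the absolute
  phase-amplitude coupling magnitudes while leaving the significance
  structure (phase-amplitude coupled, phase-phase not) intact.
* Sigma-band power of the cortical rate in the coupling-strength plane
  grows from the uncoupled to the strongly coupled corner, but not
  monotonically through the weak-coupling interior: the slow relaxation
  oscillation contributes harmonic sigma-band power of its own that weak
  thalamic drive first suppresses.
* The integrator is fixed-step forward Euler by design; no adaptive
  stepping or higher-order stochastic schemes are provided.
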