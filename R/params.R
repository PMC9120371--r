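#' Simulation grid
#'
#' Integration and output-sampling settings shared by all simulators. The
#' integration step is `dt` (forward Euler); model output is subsampled every
#' `dt_samp`, which fixes the analysis sampling rate at `1000 / dt_samp` Hz
#' (100 Hz with the defaults). `seed` is the master seed from which the
#' per-noise-source streams are derived (see [ou_process()]).
#'
#' @param duration simulated time (ms)
#' @param dt integration step (ms)
#' @param dt_samp output sampling step (ms); must be an integer multiple of
#'   `dt`
#' @param seed integer master RNG seed
#' @return an object of class `sim_grid`
#' @examples
#' sim_grid(duration = 30e3, seed = 1)
#' @export
sim_grid <- function(duration, dt = 0.01, dt_samp = 10, seed = 1L) {
  stopifnot(is.numeric(duration), duration > 0, dt > 0, dt_samp > 0)
  ratio <- dt_samp / dt
  if (abs(ratio - round(ratio)) > 1e-8)
    stop("dt_samp must be an integer multiple of dt")
  structure(list(duration = duration, dt = dt, dt_samp = dt_samp,
                 samp_every = as.integer(round(ratio)),
                 n_steps = as.integer(round(duration / dt)),
                 fs = 1000 / dt_samp, seed = as.integer(seed)),
            class = "sim_grid")
}

#' Ornstein-Uhlenbeck noise settings
#'
#' Background drive used by all nodes: `dx = (mu - x)/tau dt + sigma dW`.
#' `mu` is the mean drift (the constant input in the noise-free case),
#' `sigma` the noise amplitude (mV/ms^1.5 for the cortical currents; applied
#' to the rate-input channel for the thalamic node), `tau` the relaxation
#' time in ms.
#'
#' @param mu mean drift
#' @param sigma noise standard-deviation parameter (>= 0)
#' @param tau relaxation time (ms, > 0)
#' @return an object of class `ou_params`
#' @export
ou_params <- function(mu = 0, sigma = 0, tau = 5) {
  if (!all(is.finite(c(mu, sigma, tau)))) stop("ou_params must be finite")
  if (sigma < 0) stop("sigma must be >= 0")
  if (tau <= 0) stop("tau must be > 0")
  structure(list(mu = mu, sigma = sigma, tau = tau), class = "ou_params")
}

#' Thalamic node parameters
#'
#' Conductance-based two-population thalamic mass (TCR relay + TRN
#' reticular). Membrane potentials evolve with a leak towards `E_L`,
#' conductance-based AMPA/GABA-A synapses (alpha-kernel response, decay
#' constants `gamma_e`, `gamma_i`), and intrinsic currents: potassium leak
#' (`g_LK`), low-threshold T-type calcium (`g_T_t`, `g_T_r`; de-inactivating
#' under hyperpolarization, the rebound-burst mechanism) and, in the relay
#' population only, the anomalous rectifier I_h (`g_h`) whose
#' calcium-dependent upregulation (`g_inc`-scaled bound state) terminates
#' spindles and produces the waxing-and-waning envelope.
#'
#' Voltages in mV, conductances in mS/cm^2, times in ms, rates internally in
#' kHz (`Q_max = 0.4` = 400 Hz). Defaults follow the published
#' conductance-based thalamic mass model (Schellenberger Costa et al. 2016)
#' with T-current kinetics from Destexhe et al. (1996, 1998); the default
#' `g_LK = 0.018` places the isolated node in the spontaneously spindling
#' regime.
#'
#' @param ... name-value pairs overriding the defaults (unknown names are an
#'   error)
#' @return an object of class `thalamic_params`
#' @examples
#' p <- thalamic_params(g_LK = 0.024)
#' p$g_LK
#' @export
thalamic_params <- function(...) {
  p <- list(
    tau_t = 20, tau_r = 20,            # membrane time constants (ms)
    C_m = 1,                           # uF/cm^2
    Q_max = 400e-3,                    # max rate (kHz)
    theta = -58.5, sigma = 6,          # sigmoid threshold / gain (mV)
    C1 = pi / sqrt(3),                 # sigmoid gain factor of the source model
    gamma_e = 70e-3, gamma_i = 100e-3, # synaptic decay constants (1/ms)
    w_e = 1, w_i = 1,                  # synaptic input scalings
    E_L = -70, E_AMPA = 0, E_GABA = -70,
    E_K = -100, E_Ca = 120, E_h = -40, # reversal potentials (mV)
    g_LK = 0.018, g_T_t = 3, g_T_r = 2.3, g_h = 0.062,
    g_inc = 2,                         # conductivity scaling of bound I_h state
    alpha_Ca = -51.8e-6,               # calcium influx per unit I_T
    tau_Ca = 10, Ca_0 = 2.4e-4,        # calcium decay (ms) and baseline (mM)
    k1 = 2.5e7, k2 = 4e-4, k3 = 0.1, k4 = 1e-3, n_P = 4, # I_h Ca-binding
    N_tr = 5, N_rt = 3, N_rr = 25)     # TRN->TCR, TCR->TRN, TRN->TRN
  p <- .merge_params(p, list(...), "thalamic_params")
  stopifnot(p$Q_max > 0, p$sigma > 0, p$gamma_e > 0, p$gamma_i > 0)
  if (any(unlist(p[c("g_LK", "g_T_t", "g_T_r", "g_h")]) < 0))
    stop("conductances must be >= 0")
  structure(p, class = "thalamic_params")
}

#' Single-neuron AdEx parameters
#'
#' Exponential integrate-and-fire neuron with (optional) somatic adaptation;
#' the microscopic model behind the cortical mean-field node. These
#' parameters define the precomputed transfer functions (adaptation is
#' handled outside the tables via the mean-input shift `mu_E - I_A/C`).
#'
#' @param ... overrides of the defaults
#' @return an object of class `adex_params`
#' @export
adex_params <- function(...) {
  p <- list(
    C = 200,       # pF
    gL = 10,       # nS
    EL = -65,      # mV
    DeltaT = 1.5,  # mV, spike-initiation slope factor
    VT = -50,      # mV, exponential threshold
    Vr = -70,      # mV, reset
    Vs = -40,      # mV, spike/threshold voltage
    Tref = 1.5,    # ms, refractory
    a = 0,         # nS, subthreshold adaptation
    b = 50,        # pA, spike-triggered adaptation increment
    EA = -80,      # mV, adaptation reversal
    tauA = 400)    # ms, adaptation timescale
  p <- .merge_params(p, list(...), "adex_params")
  stopifnot(p$DeltaT > 0, p$Vr < p$Vs, p$Tref >= 0, p$C > 0, p$gL > 0)
  structure(p, class = "adex_params")
}

#' Cortical node parameters
#'
#' Mean-field model of delay-coupled excitatory (E, with spike-frequency
#' adaptation) and inhibitory (I) AdEx populations reduced to a
#' linear-nonlinear cascade: precomputed transfer functions map the mean and
#' standard deviation of the membrane input current to the population rate,
#' mean voltage and effective timescale. Mean external input drifts are
#' given in nA (`mu_E`, `mu_I`, the paper-facing convention; internally
#' divided by the membrane capacitance to mV/ms).
#'
#' Connectivity constants (`J_*` maximum synaptic currents, per-spike
#' increments `c_*`, in-degrees `K_e`/`K_i`, synaptic time constants and
#' delays) follow the published cascade model of AdEx populations (Augustin
#' et al. 2017; Cakan & Obermayer 2020). The adaptation strength `b`,
#' timescale `tauA` and the external variance contributions are set so that
#' the node reproduces the canonical NREM state space: DOWN fixed point,
#' fast E-I limit cycle at weak inhibitory drive, adaptation-driven slow
#' (<= 2 Hz) limit cycle, and UP fixed point.
#'
#' @param ... overrides of the defaults
#' @param neuron an [adex_params()] object (single-neuron basis)
#' @return an object of class `cortical_params`
#' @examples
#' cortical_params(mu_E = 0.61, mu_I = 0.4, sigma_E = 0.05, sigma_I = 0.05)
#' @export
cortical_params <- function(..., neuron = adex_params()) {
  p <- list(
    mu_E = 0.56, mu_I = 0.4,     # mean external drives (nA)
    sigma_E = 0, sigma_I = 0,    # OU noise SD (mV/ms^1.5)
    tau_ou = 5,                  # ms
    tau_se = 2, tau_si = 5,      # synaptic time constants (ms)
    cee = 0.3, cie = 0.3, cei = 0.5, cii = 0.5,  # per-spike increments
    c_ext = 0.25, K_ext = 250,   # long-range afferent channel (relay drive)
    Ke = 800, Ki = 200,          # in-degrees
    Jee = 2.43, Jie = 2.60, Jei = -3.3, Jii = -1.64,  # max currents (mV/ms)
    de = 4, di = 2,              # intracortical delays (ms)
    sigmae_ext = 1.5, sigmai_ext = 1.0)  # external variance (mV/ms^1.5)
  p <- .merge_params(p, list(...), "cortical_params")
  stopifnot(p$tau_se > 0, p$tau_si > 0, p$Ke >= 1, p$Ki >= 1, p$tau_ou > 0)
  p$neuron <- neuron
  structure(p, class = "cortical_params")
}

#' Thalamocortical loop configuration
#'
#' Coupling of the two nodes by their firing rates with a long-range delay
#' (13 ms in both directions): the cortical excitatory rate drives the AMPA
#' input of both thalamic populations with strength `N_ctx_thal`, and the
#' relay (TCR) rate enters the cortical E<-E synaptic channel with strength
#' `N_thal_ctx`. Rates cross the interface in kHz; the coupling constants
#' are the free parameters of the loop (defaults: the strong-coupling
#' parametrization used for the slow-oscillation/spindle interaction
#' analyses).
#'
#' @param N_ctx_thal corticothalamic strength (>= 0)
#' @param N_thal_ctx thalamocortical strength (>= 0)
#' @param delay long-range delay in ms (> 0), identical in both directions
#' @return an object of class `loop_config`
#' @export
loop_config <- function(N_ctx_thal = 1.2, N_thal_ctx = 0.12, delay = 13) {
  stopifnot(N_ctx_thal >= 0, N_thal_ctx >= 0, delay > 0)
  structure(list(N_ctx_thal = N_ctx_thal, N_thal_ctx = N_thal_ctx,
                 delay = delay), class = "loop_config")
}

.merge_params <- function(defaults, mods, what) {
  if (length(mods) == 0) return(defaults)
  bad <- setdiff(names(mods), names(defaults))
  if (length(bad) || is.null(names(mods)) || any(names(mods) == ""))
    stop(sprintf("unknown %s field(s): %s", what,
                 paste(bad, collapse = ", ")))
  defaults[names(mods)] <- mods
  num <- unlist(mods)
  if (!all(is.finite(num))) stop(sprintf("%s values must be finite", what))
  defaults
}

#' @export
print.sim_grid <- function(x, ...) {
  cat(sprintf(
    "<sim_grid> %.3g s simulated, dt = %g ms, output every %g ms (%g Hz), seed %d\n",
    x$duration / 1000, x$dt, x$dt_samp, x$fs, x$seed))
  invisible(x)
}

#' @export
print.thalamic_params <- function(x, ...) {
  cat(sprintf(
    "<thalamic_params> g_LK = %g, g_h = %g, g_T(t/r) = %g/%g mS/cm^2\n",
    x$g_LK, x$g_h, x$g_T_t, x$g_T_r))
  invisible(x)
}

#' @export
print.cortical_params <- function(x, ...) {
  cat(sprintf(
    "<cortical_params> mu_E = %g nA, mu_I = %g nA, sigma(E/I) = %g/%g, b = %g pA\n",
    x$mu_E, x$mu_I, x$sigma_E, x$sigma_I, x$neuron$b))
  invisible(x)
}

#' @export
print.loop_config <- function(x, ...) {
  cat(sprintf(
    "<loop_config> N_ctx->thal = %g, N_thal->ctx = %g, delay = %g ms\n",
    x$N_ctx_thal, x$N_thal_ctx, x$delay))
  invisible(x)
}
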