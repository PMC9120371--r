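#' Simulate the isolated thalamic node
#'
#' Integrates the conductance-based TCR/TRN mass model with forward Euler at
#' `grid$dt` and returns rate (Hz) and voltage (mV) series subsampled at
#' `grid$dt_samp`. Background noise enters the excitatory synaptic input of
#' the relay population as a pre-integrated Ornstein-Uhlenbeck series; an
#' optional excitatory drive (cortical rate, Hz) is added to the AMPA input
#' of both populations.
#'
#' With the default parameters the node spindles spontaneously
#' (waxing-and-waning sigma-band bursts at ~13 Hz); with `g_LK = g_h = 0.08`
#' or `g_LK = g_h = 0` it settles into constant-rate DOWN/UP fixed points.
#'
#' @param params a [thalamic_params()] object
#' @param grid a [sim_grid()] object
#' @param ou an [ou_params()] for the relay background noise (default:
#'   noise-free)
#' @param ext_rate external excitatory rate drive in Hz: a scalar, a vector
#'   at dt resolution, or a function of time (ms)
#' @param ext_strength coupling strength applied to `ext_rate`
#' @return a `tc_sim` data frame with columns `time` (s), `r_TCR`, `r_TRN`
#'   (Hz), `V_t`, `V_r` (mV)
#' @examples
#' sim <- simulate_thalamus(grid = sim_grid(8000, seed = 1))
#' range(sim$r_TCR)
#' @export
simulate_thalamus <- function(params = thalamic_params(),
                              grid = sim_grid(30e3),
                              ou = ou_params(), ext_rate = NULL,
                              ext_strength = 1) {
  stopifnot(inherits(params, "thalamic_params"), inherits(grid, "sim_grid"))
  seeds <- derive_stream_seeds(grid$seed)
  noise <- .ou_or_empty(ou, grid, seeds[1])
  ext <- .ext_series(ext_rate, grid) * ext_strength / 1000  # Hz -> kHz
  res <- sim_thalamus_cpp(unclass(params), grid$dt, grid$duration,
                          grid$samp_every, noise, ext, FALSE)
  .as_tc_sim(res[c("time", "r_TCR", "r_TRN", "V_t", "V_r")], grid,
             params = params)
}

#' Simulate the isolated cortical node
#'
#' Integrates the mean-field E-I population model: mean membrane currents
#' with transfer-function timescales, mean adaptation current (E only),
#' means and variances of the active-synapse fractions, and external
#' Ornstein-Uhlenbeck currents with drifts `params$mu_E`, `params$mu_I`
#' (nA) and noise amplitudes `params$sigma_E`, `params$sigma_I`.
#'
#' @param params a [cortical_params()] object
#' @param grid a [sim_grid()] object
#' @param table a [build_transfer_table()] result; computed (and cached for
#'   the session) when `NULL`
#' @param ext_rate optional excitatory rate drive (Hz, relay input) entering
#'   the E<-E synaptic channel; scalar, dt-resolution vector, or function of
#'   time (ms)
#' @param ext_strength coupling strength applied to `ext_rate`
#' @return a `tc_sim` data frame with columns `time` (s), `r_E`, `r_I`
#'   (Hz), `I_A` (pA)
#' @export
simulate_cortex <- function(params = cortical_params(),
                            grid = sim_grid(30e3), table = NULL,
                            ext_rate = NULL, ext_strength = 1) {
  stopifnot(inherits(params, "cortical_params"), inherits(grid, "sim_grid"))
  if (is.null(table)) table <- default_transfer_table(params$neuron)
  seeds <- derive_stream_seeds(grid$seed)
  cv <- 1000 / params$neuron$C  # nA -> mV/ms
  ou_e <- .ou_or_empty(ou_params(params$mu_E * cv, params$sigma_E,
                                 params$tau_ou), grid, seeds[2])
  ou_i <- .ou_or_empty(ou_params(params$mu_I * cv, params$sigma_I,
                                 params$tau_ou), grid, seeds[3])
  ext <- .ext_series(ext_rate, grid) * ext_strength / 1000
  res <- sim_cortex_cpp(.cx_list(params), unclass(table), grid$dt,
                        grid$duration, grid$samp_every,
                        params$mu_E * cv, params$mu_I * cv, ou_e, ou_i, ext)
  .as_tc_sim(res[c("time", "r_E", "r_I", "I_A")], grid, params = params)
}

#' Simulate the closed thalamocortical loop
#'
#' Couples the two nodes by their delayed firing rates: the cortical
#' excitatory rate drives both thalamic populations
#' (`loop$N_ctx_thal * r_E(t - delay)`) and the relay rate enters the
#' cortical E<-E channel (`loop$N_thal_ctx * r_TCR(t - delay)`), with the
#' same delay in both directions. With both strengths zero each node's
#' trajectory is bit-identical to its isolated simulation under the same
#' grid.
#'
#' @param cortex a [cortical_params()] object
#' @param thalamus a [thalamic_params()] object
#' @param loop a [loop_config()] object
#' @param grid a [sim_grid()] object
#' @param table transfer table (built and cached when `NULL`)
#' @param ou_tcr an [ou_params()] for the relay background noise
#' @return a `tc_sim` data frame with columns `time` (s), `r_E`, `r_I`,
#'   `r_TCR`, `r_TRN` (Hz), `I_A` (pA)
#' @examples
#' \donttest{
#' sim <- simulate_loop(grid = sim_grid(20e3, seed = 7))
#' }
#' @export
simulate_loop <- function(cortex = cortical_params(mu_E = 0.61, mu_I = 0.4,
                                                   sigma_E = 0.05,
                                                   sigma_I = 0.05),
                          thalamus = thalamic_params(g_LK = 0.033),
                          loop = loop_config(), grid = sim_grid(30e3),
                          table = NULL,
                          ou_tcr = ou_params(sigma = 0.005)) {
  stopifnot(inherits(cortex, "cortical_params"),
            inherits(thalamus, "thalamic_params"),
            inherits(loop, "loop_config"), inherits(grid, "sim_grid"))
  if (is.null(table)) table <- default_transfer_table(cortex$neuron)
  seeds <- derive_stream_seeds(grid$seed)
  cv <- 1000 / cortex$neuron$C
  noise_t <- .ou_or_empty(ou_tcr, grid, seeds[1])
  ou_e <- .ou_or_empty(ou_params(cortex$mu_E * cv, cortex$sigma_E,
                                 cortex$tau_ou), grid, seeds[2])
  ou_i <- .ou_or_empty(ou_params(cortex$mu_I * cv, cortex$sigma_I,
                                 cortex$tau_ou), grid, seeds[3])
  res <- sim_loop_cpp(.cx_list(cortex), unclass(table), unclass(thalamus),
                      grid$dt, grid$duration, grid$samp_every,
                      cortex$mu_E * cv, cortex$mu_I * cv,
                      loop$N_ctx_thal, loop$N_thal_ctx, loop$delay,
                      ou_e, ou_i, noise_t)
  .as_tc_sim(res[c("time", "r_E", "r_I", "r_TCR", "r_TRN", "I_A")], grid,
             params = list(cortex = cortex, thalamus = thalamus,
                           loop = loop))
}

#' Drop the startup transient of a simulation
#'
#' All statistics in the package are computed after discarding the first
#' seconds of simulated time (default 5 s).
#'
#' @param sim a `tc_sim` data frame
#' @param transient_s seconds to discard
#' @return the trimmed `tc_sim`
#' @export
drop_transient <- function(sim, transient_s = 5) {
  out <- sim[sim$time > transient_s, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("grid", "params", "fs")) attr(out, a) <- attr(sim, a)
  class(out) <- class(sim)
  out
}

#' @export
print.tc_sim <- function(x, ...) {
  g <- attr(x, "grid")
  cols <- setdiff(names(x), "time")
  cat(sprintf("<tc_sim> %d samples at %g Hz (%.3g s): %s\n", nrow(x),
              attr(x, "fs"), max(x$time), paste(cols, collapse = ", ")))
  invisible(x)
}

.as_tc_sim <- function(lst, grid, params) {
  df <- as.data.frame(lst)
  df$time <- df$time / 1000  # ms -> s
  attr(df, "grid") <- grid
  attr(df, "params") <- params
  attr(df, "fs") <- grid$fs
  class(df) <- c("tc_sim", "data.frame")
  df
}

.ou_or_empty <- function(ou, grid, seed) {
  stopifnot(inherits(ou, "ou_params"))
  if (ou$sigma == 0 && ou$mu == 0) return(numeric(0))
  if (ou$sigma == 0) return(ou$mu)  # constant drive, broadcast in C++
  g <- grid
  g$seed <- seed
  class(g) <- "sim_grid"
  ou_process(ou, g)
}

.ext_series <- function(ext_rate, grid) {
  if (is.null(ext_rate)) return(numeric(0))
  if (is.function(ext_rate)) {
    tt <- (seq_len(grid$n_steps) - 1) * grid$dt
    ext_rate <- ext_rate(tt)
  }
  if (length(ext_rate) == 1) return(as.numeric(ext_rate))
  if (length(ext_rate) < grid$n_steps)
    stop("ext_rate must be scalar or have one value per integration step")
  as.numeric(ext_rate)
}

.cx_list <- function(params) {
  n <- params$neuron
  list(C = n$C, a = n$a, b = n$b, EA = n$EA, tauA = n$tauA,
       taum = n$C / n$gL,
       tau_se = params$tau_se, tau_si = params$tau_si,
       cee = params$cee, cie = params$cie, cei = params$cei,
       cii = params$cii, c_ext = params$c_ext, K_ext = params$K_ext,
       Ke = params$Ke, Ki = params$Ki,
       Jee = params$Jee, Jie = params$Jie, Jei = params$Jei,
       Jii = params$Jii, de = params$de, di = params$di,
       sigmae_ext = params$sigmae_ext, sigmai_ext = params$sigmai_ext)
}
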