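#' Precompute the cortical transfer functions
#'
#' Steady-state rate, mean membrane voltage and effective timescale of an
#' exponential integrate-and-fire population driven by white noise with mean
#' `mu` (mV/ms) and standard deviation `sigma` (mV/ms^1.5), tabulated on a
#' rectangular grid by threshold integration of the stationary
#' Fokker-Planck equation; the timescale is the exponential-kernel fit to
#' the linear rate response (computed at `fit_freqs` Hz). Population
#' equations interpolate these tables bilinearly with clamped extrapolation;
#' adaptation enters outside the table through the shift
#' `mu_E - I_A / C`.
#'
#' @param neuron an [adex_params()] object
#' @param mu_grid,sigma_grid strictly increasing, uniformly spaced axes
#' @param V_lb lower bound of the membrane-voltage integration grid (mV)
#' @param dV voltage step of the integration grid (mV)
#' @param fit_freqs frequencies (Hz) used for the timescale fit
#' @return an object of class `transfer_table`
#' @examples
#' tb <- build_transfer_table(adex_params(), mu_grid = seq(0, 4, 0.5),
#'                            sigma_grid = c(1, 2))
#' lookup_transfer(tb, mu = 2.1, sigma = 1.5)
#' @export
build_transfer_table <- function(neuron = adex_params(),
                                 mu_grid = seq(-2, 8, by = 0.05),
                                 sigma_grid = seq(0.05, 5.05, by = 0.25),
                                 V_lb = -200, dV = 0.05,
                                 fit_freqs = c(1, 2, 5, 10, 20, 50, 100, 200)) {
  stopifnot(inherits(neuron, "adex_params"))
  if (length(mu_grid) < 2 || length(sigma_grid) < 2)
    stop("grids need at least two points per axis")
  if (any(diff(mu_grid) <= 0) || any(diff(sigma_grid) <= 0))
    stop("grids must be strictly increasing")
  tb <- build_transfer_table_cpp(unclass(neuron), mu_grid, sigma_grid,
                                 V_lb, dV, fit_freqs)
  tb$neuron <- neuron
  structure(tb, class = "transfer_table")
}

#' Interpolate a transfer table
#'
#' Bilinear interpolation of rate (kHz), mean voltage (mV) and effective
#' timescale (ms); queries outside the grid are clamped to the boundary.
#'
#' @param table a [build_transfer_table()] result
#' @param mu,sigma query points (recycled to common length)
#' @return list with numeric vectors `r`, `V`, `tau`
#' @export
lookup_transfer <- function(table, mu, sigma) {
  stopifnot(inherits(table, "transfer_table"))
  n <- max(length(mu), length(sigma))
  lookup_transfer_cpp(unclass(table), rep_len(as.numeric(mu), n),
                      rep_len(as.numeric(sigma), n))
}

#' Monte-Carlo population rate of independent EIF neurons
#'
#' Brute-force oracle for the Fokker-Planck tables: simulates `n_neuron`
#' independent exponential integrate-and-fire neurons (no adaptation) under
#' white noise and returns the population rate in Hz.
#'
#' @param neuron an [adex_params()] object
#' @param mu,sigma input mean (mV/ms) and SD (mV/ms^1.5)
#' @param n_neuron number of neurons
#' @param t_total simulated time per neuron (ms)
#' @param dt integration step (ms)
#' @param t_burn initial time excluded from the spike count (ms)
#' @param seed RNG seed
#' @return population rate (Hz)
#' @export
mc_eif_rate <- function(neuron, mu, sigma, n_neuron = 2000, t_total = 5000,
                        dt = 0.02, t_burn = 1000, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  1000 * mc_eif_rate_cpp(unclass(neuron), mu, sigma, n_neuron, t_total, dt,
                         t_burn)[1]
}

#' @export
print.transfer_table <- function(x, ...) {
  cat(sprintf(
    "<transfer_table> %d mu x %d sigma points, mu in [%g, %g] mV/ms, sigma in [%g, %g]\n",
    length(x$mu_grid), length(x$sigma_grid), min(x$mu_grid), max(x$mu_grid),
    min(x$sigma_grid), max(x$sigma_grid)))
  invisible(x)
}

# session-cached default table for the given neuron parameters
default_transfer_table <- function(neuron = adex_params()) {
  key <- paste(unlist(neuron[c("C", "gL", "EL", "DeltaT", "VT", "Vr", "Vs",
                               "Tref")]), collapse = "|")
  hit <- .sl_cache[[key]]
  if (!is.null(hit)) return(hit)
  tb <- build_transfer_table(neuron)
  .sl_cache[[key]] <- tb
  tb
}
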