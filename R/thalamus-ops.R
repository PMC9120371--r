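#' Thalamic sigmoidal firing-rate function
#'
#' Converts a mean membrane potential to a population rate,
#' `Q_max / (1 + exp(-C1 (V - theta) / sigma))`, strictly increasing in V
#' and saturating at `Q_max`.
#'
#' @param V membrane potential (mV), vectorized
#' @param params a [thalamic_params()] object
#' @return firing rate in Hz
#' @examples
#' p <- thalamic_params()
#' thalamic_rate(p$theta, p)  # half the maximum rate
#' @export
thalamic_rate <- function(V, params = thalamic_params()) {
  stopifnot(all(is.finite(V)))
  1000 * params$Q_max / (1 + exp(-params$C1 * (V - params$theta) / params$sigma))
}

# steady-state gating functions and voltage-dependent time constants of the
# intrinsic currents (relay-cell T current after Destexhe et al. 1998,
# reticular T current after Destexhe et al. 1996, anomalous rectifier after
# Destexhe et al. 1996); the /3.7371928 factor is the temperature
# adjustment of the inactivation time constants
thalamic_gates <- function(V, population = c("TCR", "TRN")) {
  population <- match.arg(population)
  if (population == "TCR") {
    list(m_inf = 1 / (1 + exp(-(V + 59) / 6.2)),
         h_inf = 1 / (1 + exp((V + 81) / 4)),
         tau_h = (30.8 + (211.4 + exp((V + 115.2) / 5)) /
                    (1 + exp((V + 86) / 3.2))) / 3.7371928,
         m_inf_h = 1 / (1 + exp((V + 75) / 5.5)),
         tau_m_h = 20 + 1000 / (exp((V + 71.5) / 14.2) +
                                  exp(-(V + 89) / 11.6)))
  } else {
    list(m_inf = 1 / (1 + exp(-(V + 52) / 7.4)),
         h_inf = 1 / (1 + exp((V + 80) / 5)),
         tau_h = (85 + 1 / (exp((V + 48) / 4) +
                              exp(-(V + 407) / 50))) / 3.7371928)
  }
}

#' Intrinsic membrane currents of a thalamic population
#'
#' Potassium leak `I_LK = g_LK (V - E_K)`, T-type calcium current
#' `I_T = g_T m_inf^2 h (V - E_Ca)` (instantaneous activation, dynamic
#' inactivation `h`), and for the relay population only the anomalous
#' rectifier `I_h = g_h (m_h1 + g_inc m_h2)(V - E_h)`.
#'
#' @param V membrane potential (mV)
#' @param h T-current inactivation gate in \[0, 1\]
#' @param params a [thalamic_params()] object
#' @param population `"TCR"` or `"TRN"`
#' @param m_h1,m_h2 unbound/calcium-bound open fractions of I_h (TCR only)
#' @return list with `I_LK`, `I_T` and (TCR) `I_h`, in uA/cm^2
#' @export
thalamic_currents <- function(V, h, params = thalamic_params(),
                              population = c("TCR", "TRN"),
                              m_h1 = 0, m_h2 = 0) {
  population <- match.arg(population)
  g <- thalamic_gates(V, population)
  out <- list(
    I_LK = params$g_LK * (V - params$E_K),
    I_T = (if (population == "TCR") params$g_T_t else params$g_T_r) *
      g$m_inf^2 * h * (V - params$E_Ca))
  if (population == "TCR")
    out$I_h <- params$g_h * (m_h1 + params$g_inc * m_h2) * (V - params$E_h)
  out
}
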