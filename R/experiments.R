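#' Mean band power from the Welch spectrum
#'
#' @param signal series
#' @param fs sampling rate (Hz)
#' @param band `c(low, high)` Hz, inside the Nyquist range
#' @param window_s Welch segment length (s)
#' @return mean power spectral density within the band
#' @export
band_power <- function(signal, fs, band, window_s = 4) {
  if (band[2] > fs / 2) stop("band outside Nyquist range")
  sp <- welch_psd(signal, fs, window_s)
  keep <- sp$freq >= band[1] & sp$freq <= band[2]
  mean(sp$psd[keep])
}

#' Detect cortical DOWN states
#'
#' Intervals where the excitatory rate stays below an adaptive threshold
#' (the 5th percentile plus `frac` of the 5th-95th percentile range) for at
#' least `min_dwell` seconds. The rule is scale-free across
#' parametrizations.
#'
#' @param signal excitatory rate series (or `tc_sim`, column `r_E`)
#' @param fs sampling rate (Hz)
#' @param frac threshold position within the percentile range
#' @param min_dwell minimum DOWN duration (s)
#' @return data frame with `start`, `end`, `midpoint` (s)
#' @export
detect_down_states <- function(signal, fs = 100, frac = 0.25,
                               min_dwell = 0.1) {
  t_offset <- 0
  if (inherits(signal, "tc_sim")) {
    fs <- attr(signal, "fs")
    t_offset <- signal$time[1]
    signal <- signal$r_E
  }
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      midpoint = numeric(0))
  q <- quantile(signal, c(0.05, 0.95), names = FALSE)
  if (diff(q) < 1e-9) return(empty)
  thr <- q[1] + frac * diff(q)
  ev <- .runs_to_events(signal < thr, fs, merge_gap = 0)
  ev <- ev[ev$duration >= min_dwell, , drop = FALSE]
  if (nrow(ev) == 0) return(empty)
  data.frame(start = ev$start + t_offset, end = ev$end + t_offset,
             midpoint = (ev$start + ev$end) / 2 + t_offset)
}

#' Pair DOWN states with following spindles
#'
#' A DOWN state counts as "spindle-followed" when a detected spindle peak
#' occurs within `window` seconds after its midpoint.
#'
#' @param down a [detect_down_states()] result
#' @param spindles a [detect_spindles()] result
#' @param window pairing window (s)
#' @return `down` with logical column `followed` and numeric `delay` (s,
#'   NA when not followed)
#' @export
pair_down_spindles <- function(down, spindles, window = 1.5) {
  if (nrow(down) == 0) {
    down$followed <- logical(0); down$delay <- numeric(0)
    return(down)
  }
  delay <- vapply(down$midpoint, function(m) {
    d <- spindles$peak_time - m
    d <- d[d >= 0 & d <= window]
    if (length(d)) min(d) else NA_real_
  }, numeric(1))
  down$followed <- !is.na(delay)
  down$delay <- delay
  down
}

#' Event-locked average with standard error
#'
#' @param signal series
#' @param fs sampling rate (Hz)
#' @param event_times event times (s); events whose window leaves the
#'   series are dropped
#' @param window `c(before, after)` in s (before <= 0 <= after)
#' @return list with `lag` (s), `mean`, `sem`, `n_events`
#' @export
event_locked_average <- function(signal, fs, event_times,
                                 window = c(-2, 2)) {
  n <- length(signal)
  i0 <- round(window[1] * fs); i1 <- round(window[2] * fs)
  idx <- round(event_times * fs)
  idx <- idx[idx + i0 >= 1 & idx + i1 <= n]
  if (length(idx) < 2) stop("fewer than two usable events")
  segs <- vapply(idx, function(i) signal[(i + i0):(i + i1)],
                 numeric(i1 - i0 + 1))
  m <- rowMeans(segs)
  sem <- apply(segs, 1, sd) / sqrt(length(idx))
  list(lag = (i0:i1) / fs, mean = m, sem = sem, n_events = length(idx))
}

#' Circular statistics of a phase sample
#'
#' Circular mean (argument of the resultant), circular SD
#' `sqrt(-2 log R)` with R the resultant length, and a histogram over
#' (-pi, pi].
#'
#' @param phases radians
#' @param n_bins histogram bins
#' @return list with `mean`, `sd`, `R`, `histogram` (counts), `breaks`
#' @export
circular_phase_stats <- function(phases, n_bins = 18) {
  if (length(phases) == 0) stop("empty input")
  z <- mean(exp(1i * phases))
  R <- Mod(z)
  breaks <- seq(-pi, pi, length.out = n_bins + 1)
  h <- hist(((phases + pi) %% (2 * pi)) - pi, breaks = breaks,
            plot = FALSE)$counts
  list(mean = Arg(z), sd = sqrt(-2 * log(max(R, 1e-300))), R = R,
       histogram = h, breaks = breaks)
}

#' Synthetic phase-amplitude-coupled test signal
#'
#' `A_s cos(2 pi f_s t) + A_f (1 + m cos(2 pi f_s t - phi0))
#' sin(2 pi f_f t) + noise`: a slow carrier plus a fast oscillation whose
#' envelope is modulated by the slow phase with depth `m` and preferred
#' phase `phi0` (the Hilbert phase of the slow component at which the fast
#' amplitude peaks equals `phi0` by construction).
#'
#' With `modulator = "cosine"` the slow carrier is deterministic — ideal
#' for recovering `m` and `phi0`, but note that spectrum-preserving
#' surrogates of such a near-periodic signal are close to time shifts of
#' it, against which shift-invariant coupling statistics have no power.
#' `modulator = "noise"` replaces the slow carrier by narrowband Gaussian
#' noise around `f_slow` (coupling defined on its Hilbert phase), giving an
#' aperiodic fixture appropriate for surrogate significance tests.
#'
#' @param f_slow,f_fast component frequencies (Hz)
#' @param m modulation depth in \[0, 1\]
#' @param phi0 preferred coupling phase (rad)
#' @param A_slow,A_fast component amplitudes
#' @param noise_sd additive white-noise SD
#' @param duration_s,fs length (s) and sampling rate (Hz)
#' @param seed RNG seed
#' @param modulator `"cosine"` (deterministic slow carrier) or `"noise"`
#'   (narrowband stochastic slow carrier)
#' @return numeric series with attributes `m`, `phi0`, `fs`
#' @export
generate_pac_signal <- function(f_slow = 1, f_fast = 13.5, m = 0.5,
                                phi0 = 0, A_slow = 1, A_fast = 0.5,
                                noise_sd = 0.1, duration_s = 120, fs = 100,
                                seed = 1,
                                modulator = c("cosine", "noise")) {
  if (m < 0 || m > 1) stop("m must be in [0, 1]")
  if (f_slow >= f_fast) stop("need f_slow < f_fast")
  modulator <- match.arg(modulator)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  if (modulator == "cosine") {
    slow <- A_slow * cos(2 * pi * f_slow * t)
    phase_slow <- 2 * pi * f_slow * t
  } else {
    raw <- fir_bandpass(rnorm(length(t)), fs, c(f_slow / 2, f_slow * 1.5))
    slow <- A_slow * raw / stats::sd(raw)
    phase_slow <- Arg(hilbert_analytic(slow))
  }
  x <- slow +
    A_fast * (1 + m * cos(phase_slow - phi0)) * sin(2 * pi * f_fast * t) +
    rnorm(length(t), sd = noise_sd)
  structure(x, m = m, phi0 = phi0, fs = fs)
}

#' Synthetic spindle train
#'
#' Gaussian-envelope sigma-band bursts on a white-noise background, with
#' the ground-truth events stored as an attribute.
#'
#' @param burst_times burst centre times (s); bursts must not overlap
#' @param burst_dur full width at half maximum of the envelope (s)
#' @param carrier burst carrier frequency (Hz)
#' @param amp burst peak amplitude (in units of the noise SD)
#' @param noise_sd background noise SD
#' @param duration_s,fs length (s) and sampling rate (Hz)
#' @param seed RNG seed
#' @return numeric series with attribute `events` (data frame of centre,
#'   onset, offset at the half-maximum level) and `fs`
#' @export
generate_spindle_train <- function(burst_times, burst_dur = 0.6,
                                   carrier = 13, amp = 10, noise_sd = 1,
                                   duration_s = 60, fs = 100, seed = 1) {
  if (length(burst_times) > 1 &&
      any(diff(sort(burst_times)) < burst_dur))
    stop("bursts overlap")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  x <- rnorm(length(t), sd = noise_sd)
  env_sd <- burst_dur / (2 * sqrt(2 * log(2)))  # FWHM -> SD
  for (bc in burst_times) {
    env <- amp * noise_sd * exp(-(t - bc)^2 / (2 * env_sd^2))
    x <- x + env * sin(2 * pi * carrier * (t - bc))
  }
  events <- data.frame(centre = burst_times,
                       onset = burst_times - burst_dur / 2,
                       offset = burst_times + burst_dur / 2)
  structure(x, events = events, fs = fs)
}

# ------------------------------------------------------------------ sweeps

#' Sweep specification
#'
#' @param type `"thalamus"`, `"cortex"` or `"loop"`
#' @param axes named list of parameter vectors; for `thalamus`:
#'   `g_LK`, `g_h`, optional `sigma`; for `cortex`: `mu_E`, `mu_I`; for
#'   `loop`: `N_thal_ctx`, `N_ctx_thal`
#' @param grid per-point [sim_grid()] (seed reused at each point)
#' @param transient_s seconds discarded before statistics
#' @param ... extra fixed arguments passed to the per-point simulator
#'   (`params`, `table`, ...)
#' @return object of class `sweep_spec`
#' @export
sweep_spec <- function(type = c("thalamus", "cortex", "loop"), axes,
                       grid = sim_grid(30e3), transient_s = 5, ...) {
  type <- match.arg(type)
  stopifnot(is.list(axes), !is.null(names(axes)))
  if (any(lengths(axes) < 1)) stop("empty sweep axis")
  structure(list(type = type, axes = axes, grid = grid,
                 transient_s = transient_s, extra = list(...)),
            class = "sweep_spec")
}

#' Run a parameter sweep
#'
#' Simulates every point of the axis product independently (order never
#' affects results: the same grid seed is applied at each point) and
#' returns one row per point in long format. Points whose simulation
#' diverges are recorded with `NA` summaries rather than failing the
#' sweep.
#'
#' Summaries: thalamic sweeps report detected spindles per second (on the
#' relay rate, transient excluded) and the dominant sigma-band frequency;
#' cortical sweeps report the maximum rate, dominant frequency and
#' peak-to-peak amplitude of the excitatory rate; loop sweeps additionally
#' report mean Welch power in the slow-oscillation (0.1-3 Hz) and fast
#' spindle (12-15 Hz) bands.
#'
#' @param spec a [sweep_spec()]
#' @return long-format data frame
#' @export
run_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  pts <- expand.grid(spec$axes, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(pts)), function(i) {
    point <- as.list(pts[i, , drop = FALSE])
    res <- tryCatch(.sweep_point(spec, point), error = function(e) NULL)
    if (is.null(res)) res <- list()
    c(point, res)
  })
  all_names <- unique(unlist(lapply(rows, names)))
  out <- do.call(rbind, lapply(rows, function(r) {
    r[setdiff(all_names, names(r))] <- NA_real_
    as.data.frame(r[all_names])
  }))
  rownames(out) <- NULL
  out
}

.sweep_point <- function(spec, point) {
  g <- spec$grid
  tr <- spec$transient_s
  if (spec$type == "thalamus") {
    par_args <- point[intersect(names(point), c("g_LK", "g_h"))]
    base <- spec$extra$params
    params <- if (is.null(base)) do.call(thalamic_params, par_args) else {
      q <- unclass(base); q[names(par_args)] <- par_args
      do.call(thalamic_params, q)
    }
    ou <- if (!is.null(point$sigma)) ou_params(sigma = point$sigma) else
      ou_params()
    sim <- simulate_thalamus(params, g, ou = ou,
                             ext_rate = spec$extra$ext_rate,
                             ext_strength = if (is.null(spec$extra$ext_strength)) 1
                                            else spec$extra$ext_strength)
    x <- drop_transient(sim, tr)$r_TCR
    ev <- detect_spindles(x, fs = g$fs)
    dens <- spindle_density(ev, max(sim$time) - tr)
    list(spindles_per_second = dens$per_second,
         sigma_peak_hz = dominant_frequency(x, g$fs, band = c(9, 16)))
  } else if (spec$type == "cortex") {
    params <- cortical_params(mu_E = point$mu_E, mu_I = point$mu_I)
    sim <- simulate_cortex(params, g, table = spec$extra$table)
    x <- drop_transient(sim, tr)$r_E
    list(max_rate = max(x),
         dominant_freq = dominant_frequency(x, g$fs),
         amplitude = max(x) - min(x))
  } else {
    cortex <- spec$extra$cortex
    if (is.null(cortex)) cortex <- cortical_params()
    if (!is.null(point$mu_E)) {
      q <- unclass(cortex); q$mu_E <- point$mu_E
      if (!is.null(point$mu_I)) q$mu_I <- point$mu_I
      neuron <- q$neuron; q$neuron <- NULL
      cortex <- do.call(cortical_params, c(q, list(neuron = neuron)))
    }
    thal <- spec$extra$thalamus
    if (is.null(thal)) thal <- thalamic_params(g_LK = 0.033)
    lp <- loop_config(N_ctx_thal = if (is.null(point$N_ctx_thal)) 1.2
                                   else point$N_ctx_thal,
                      N_thal_ctx = if (is.null(point$N_thal_ctx)) 0.12
                                   else point$N_thal_ctx)
    ou_tcr <- spec$extra$ou_tcr
    if (is.null(ou_tcr)) ou_tcr <- ou_params()
    sim <- simulate_loop(cortex, thal, lp, g, table = spec$extra$table,
                         ou_tcr = ou_tcr)
    x <- drop_transient(sim, tr)$r_E
    list(max_rate = max(x),
         dominant_freq = dominant_frequency(x, g$fs),
         amplitude = max(x) - min(x),
         so_power = band_power(x, g$fs, c(0.1, 3)),
         sigma_power = band_power(x, g$fs, c(12, 15)))
  }
}

#' Short-time Fourier transform magnitude
#'
#' Hann-windowed STFT (2 s default window) as used for the time-frequency
#' views of the rate series.
#'
#' @param signal series
#' @param fs sampling rate (Hz)
#' @param window_s window length (s)
#' @param step_s hop (s)
#' @return list with `time` (s), `freq` (Hz), `power` (freq x time matrix)
#' @export
stft_power <- function(signal, fs, window_s = 2, step_s = 0.1) {
  L <- round(window_s * fs)
  step <- max(1, round(step_s * fs))
  n <- length(signal)
  if (n < L) stop("signal shorter than one window")
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1))
  starts <- seq(1, n - L + 1, by = step)
  nf <- floor(L / 2) + 1
  P <- matrix(NA_real_, nf, length(starts))
  for (j in seq_along(starts)) {
    seg <- signal[starts[j]:(starts[j] + L - 1)]
    seg <- (seg - mean(seg)) * w
    P[, j] <- (Mod(fft(seg))^2)[1:nf]
  }
  list(time = (starts + L / 2 - 1) / fs, freq = seq(0, floor(L / 2)) * fs / L,
       power = P)
}
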