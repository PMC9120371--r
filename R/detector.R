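#' Spindle detector configuration
#'
#' A7-style sigma-band detector operating on model rate series. Three
#' decision streams are computed on the z-scored signal: relative sigma
#' power (STFT, 2 s windows, 200 ms steps), moving correlation between the
#' sigma-filtered and broadband signals, and moving RMS of the sigma
#' envelope (300 ms windows, 100 ms steps); samples where all three streams
#' exceed threshold seed candidate events, which are merged across gaps
#' shorter than `merge_gap`, refined on the sigma envelope and filtered by
#' duration.
#'
#' For model output two thresholds are relaxed relative to the published
#' EEG defaults: `min_duration` 0.5 -> 0.3 s and `rel_power_threshold`
#' 0.2 -> 0.15 (`preset = "cortical"`); the remaining constants keep the
#' published A7 defaults (correlation 0.65, RMS mean + 1.5 SD, maximum
#' duration 2.5 s).
#'
#' @param preset `"default"` (EEG-style thresholds) or `"cortical"`
#'   (relaxed thresholds for model rates)
#' @param ... overrides of individual fields: `sigma_band`, `broad_band`,
#'   `min_duration`, `max_duration`, `rel_power_threshold`,
#'   `corr_threshold`, `rms_sd_threshold`, `merge_gap`
#' @return an object of class `detector_config`
#' @export
detector_config <- function(preset = c("default", "cortical"), ...) {
  preset <- match.arg(preset)
  cfg <- list(sigma_band = c(12, 15), broad_band = c(1, 30),
              min_duration = 0.5, max_duration = 2.5,
              rel_power_threshold = 0.2, corr_threshold = 0.65,
              rms_sd_threshold = 1.5, merge_gap = 0.5)
  if (preset == "cortical") {
    cfg$min_duration <- 0.3
    cfg$rel_power_threshold <- 0.15
  }
  cfg <- .merge_params(cfg, list(...), "detector_config")
  if (cfg$min_duration <= 0 || cfg$min_duration >= cfg$max_duration)
    stop("need 0 < min_duration < max_duration")
  if (cfg$rel_power_threshold < 0 || cfg$corr_threshold < 0)
    stop("thresholds must be >= 0")
  structure(cfg, class = "detector_config")
}

.moving_stat <- function(n, fs, window_s, step_s, fun) {
  L <- max(2, round(window_s * fs))
  step <- max(1, round(step_s * fs))
  starts <- seq(1, max(1, n - L + 1), by = step)
  centers <- starts + (L - 1) / 2
  vals <- vapply(starts, function(s) fun(s, min(s + L - 1, n)), numeric(1))
  approx(centers, vals, xout = seq_len(n), rule = 2)$y
}

#' Detect sleep spindles in a rate series
#'
#' @param signal numeric rate series (or a `tc_sim`; then `column` selects
#'   the series and `fs` is taken from the object)
#' @param fs sampling rate in Hz (default 100, the analysis rate of the
#'   simulators)
#' @param config a [detector_config()]
#' @param column column used when `signal` is a `tc_sim`
#' @return data frame of class `spindle_events` with columns `start`,
#'   `end`, `duration`, `peak_time` (s), `mean_frequency` (Hz),
#'   `peak_amplitude` (z-units); zero rows if nothing is detected
#' @examples
#' x <- generate_spindle_train(burst_times = c(2, 6), duration_s = 10,
#'                             seed = 1)
#' detect_spindles(x)
#' @export
detect_spindles <- function(signal, fs = 100,
                            config = detector_config("cortical"),
                            column = "r_TCR") {
  t_offset <- 0
  if (inherits(signal, "tc_sim")) {
    fs <- attr(signal, "fs")
    t_offset <- signal$time[1]  # absolute event times for trimmed series
    signal <- signal[[column]]
  }
  stopifnot(inherits(config, "detector_config"))
  n <- length(signal)
  if (n < 3 * fs) stop("signal shorter than the analysis window (3 s)")
  sdv <- sd(signal)
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0), peak_time = numeric(0),
                      mean_frequency = numeric(0),
                      peak_amplitude = numeric(0))
  class(empty) <- c("spindle_events", "data.frame")
  if (!is.finite(sdv) || sdv < 1e-12) return(empty)

  x <- (signal - mean(signal)) / sdv
  broad <- fir_bandpass(x, fs, config$broad_band)
  sig <- fir_bandpass(x, fs, config$sigma_band)

  # stream 1: relative sigma power from a short-time spectrum
  relpow <- .moving_stat(n, fs, 2, 0.2, function(a, b) {
    seg <- x[a:b]
    sp <- welch_psd(seg, fs, window_s = (b - a + 1) / fs)
    num <- sum(sp$psd[sp$freq >= config$sigma_band[1] &
                      sp$freq <= config$sigma_band[2]])
    den <- sum(sp$psd[sp$freq >= config$broad_band[1] &
                      sp$freq <= config$broad_band[2]])
    if (den <= 0) 0 else num / den
  })
  # stream 2: moving correlation sigma vs broadband
  mcorr <- .moving_stat(n, fs, 0.3, 0.1, function(a, b) {
    sa <- sig[a:b]; sb <- broad[a:b]
    if (sd(sa) < 1e-12 || sd(sb) < 1e-12) 0 else stats::cor(sa, sb)
  })
  # stream 3: moving RMS of the sigma-filtered signal
  mrms <- .moving_stat(n, fs, 0.3, 0.1, function(a, b)
    sqrt(mean(sig[a:b]^2)))
  rms_thr <- mean(mrms) + config$rms_sd_threshold * sd(mrms)

  # conjunctive decision (all streams above threshold): on model rate
  # series the spectral streams saturate and the envelope stream carries
  # the discrimination, while on noisy signals the correlation stream
  # suppresses chance sigma-power fluctuations
  active <- (relpow > config$rel_power_threshold) &
    (mcorr > config$corr_threshold) & (mrms > rms_thr)

  # raw supra-threshold cores must persist before they are kept: brief
  # chance coincidences of the decision streams (fractions of the minimum
  # spindle duration) are discarded prior to merging and refinement
  cores <- .runs_to_events(active, fs, merge_gap = 0)
  cores <- cores[cores$duration >= max(0.15, config$min_duration / 2), ,
                 drop = FALSE]
  if (nrow(cores) == 0) return(empty)
  ev <- .merge_events(cores, config$merge_gap)

  # refine each candidate on the sigma envelope: boundaries are the
  # crossings of max(soft envelope threshold, half the event's own peak),
  # which makes the reported duration the width of the waxing-waning
  # envelope at the detection level
  env <- Mod(hilbert_analytic(sig))
  soft <- mean(env) + 0.5 * sd(env)
  ref <- lapply(seq_len(nrow(ev)), function(i) {
    a <- max(1, round(ev$start[i] * fs) + 1)
    b <- min(n, round(ev$end[i] * fs))
    pk <- a + which.max(env[a:b]) - 1
    level <- max(soft, env[pk] / 2)
    lo <- pk; while (lo > 1 && env[lo - 1] >= level) lo <- lo - 1
    hi <- pk; while (hi < n && env[hi + 1] >= level) hi <- hi + 1
    c(lo, hi, pk)
  })
  ref <- unique(do.call(rbind, ref))
  # drop refined events nested in (or overlapping) an earlier one
  keep <- rep(TRUE, nrow(ref))
  if (nrow(ref) > 1) {
    for (i in 2:nrow(ref)) keep[i] <- ref[i, 1] > max(ref[keep & seq_len(nrow(ref)) < i, 2])
  }
  ref <- ref[keep, , drop = FALSE]

  inst_f <- c(NA, diff(Arg(hilbert_analytic(sig)))) / (2 * pi) * fs
  inst_f[!is.na(inst_f) & inst_f < 0] <- NA  # phase wraps
  out <- do.call(rbind, lapply(seq_len(nrow(ref)), function(i) {
    a <- ref[i, 1]; b <- ref[i, 2]; pk <- ref[i, 3]
    data.frame(start = (a - 1) / fs, end = b / fs,
               duration = (b - a + 1) / fs, peak_time = pk / fs,
               mean_frequency = median(inst_f[a:b], na.rm = TRUE),
               peak_amplitude = env[pk])
  }))
  out <- out[out$duration >= config$min_duration &
             out$duration <= config$max_duration, , drop = FALSE]
  out$start <- out$start + t_offset
  out$end <- out$end + t_offset
  out$peak_time <- out$peak_time + t_offset
  rownames(out) <- NULL
  class(out) <- c("spindle_events", "data.frame")
  out
}

.runs_to_events <- function(active, fs, merge_gap) {
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  on <- which(r$values)
  if (length(on) == 0)
    return(data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0)))
  ev <- data.frame(start = (starts[on] - 1) / fs, end = ends[on] / fs)
  .merge_events(ev, merge_gap)
}

# merge events separated by gaps shorter than merge_gap (seconds)
.merge_events <- function(ev, merge_gap) {
  merged <- ev[1, c("start", "end"), drop = FALSE]
  if (nrow(ev) > 1) {
    for (i in 2:nrow(ev)) {
      if (ev$start[i] - merged$end[nrow(merged)] < merge_gap) {
        merged$end[nrow(merged)] <- ev$end[i]
      } else {
        merged <- rbind(merged, ev[i, c("start", "end")])
      }
    }
  }
  merged$duration <- merged$end - merged$start
  merged
}

#' Spindle density
#'
#' @param events a [detect_spindles()] result
#' @param duration_s length of the analysed (post-transient) signal in s
#' @return list with `per_second` and `per_minute`
#' @export
spindle_density <- function(events, duration_s) {
  if (duration_s <= 0) stop("duration must be positive")
  n <- nrow(events)
  list(per_second = n / duration_s, per_minute = 60 * n / duration_s)
}

#' @export
print.spindle_events <- function(x, ...) {
  cat(sprintf("<spindle_events> %d event(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(x, digits = 4)
  invisible(x)
}
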