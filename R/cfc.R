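#' Band-limited instantaneous phase and amplitude
#'
#' Zero-phase FIR bandpass followed by the Hilbert transform. Phase follows
#' the `atan2(imag, real)` convention in (-pi, pi]; amplitude is the
#' analytic-signal envelope. The canonical bands are 0.1-3 Hz for the slow
#' oscillation and 12-15 Hz for fast spindles.
#'
#' @param signal raw series
#' @param fs sampling rate (Hz)
#' @param band `c(low, high)` Hz
#' @return object of class `analytic_signal`: list with `phase`,
#'   `amplitude`, `filtered`, `band`, `fs`
#' @export
band_phase_amplitude <- function(signal, fs, band) {
  if (band[1] <= 0 || band[2] >= fs / 2) stop("band outside (0, fs/2)")
  # demean first: the truncated FIR kernel has a small nonzero DC gain, and
  # removing the mean makes the result invariant to constant offsets
  f <- fir_bandpass(signal - mean(signal), fs, band)
  a <- hilbert_analytic(f)
  structure(list(phase = Arg(a), amplitude = Mod(a), filtered = f,
                 band = band, fs = fs), class = "analytic_signal")
}

#' @export
print.analytic_signal <- function(x, ...) {
  cat(sprintf("<analytic_signal> %d samples at %g Hz, band %g-%g Hz\n",
              length(x$phase), x$fs, x$band[1], x$band[2]))
  invisible(x)
}

#' Kullback-Leibler modulation index
#'
#' Phase-amplitude coupling strength: mean amplitude per phase bin,
#' normalized to a distribution P, and `(log N - H(P)) / log N` where H is
#' the Shannon entropy. 0 for amplitude independent of phase, 1 when all
#' amplitude mass falls into a single bin.
#'
#' @param phase phase series (radians), e.g. the slow-oscillation phase
#' @param amplitude amplitude series, e.g. the spindle envelope
#' @param n_bins number of phase bins
#' @return scalar in \[0, 1\]
#' @export
kl_mi <- function(phase, amplitude, n_bins = 18) {
  stopifnot(length(phase) == length(amplitude), n_bins >= 2)
  if (all(amplitude == 0)) stop("amplitude is identically zero")
  bins <- .phase_bins(phase, n_bins)
  m <- vapply(seq_len(n_bins),
              function(b) if (any(bins == b)) mean(amplitude[bins == b]) else 0,
              numeric(1))
  P <- m / sum(m)
  H <- -sum(P[P > 0] * log(P[P > 0]))
  (log(n_bins) - H) / log(n_bins)
}

.phase_bins <- function(phase, n_bins) {
  b <- floor((phase + pi) / (2 * pi) * n_bins) + 1
  pmin(pmax(b, 1L), n_bins)
}

#' Mean vector length
#'
#' Amplitude-weighted mean phase vector `mean(A(t) exp(i phi(t)))`
#' (time-average normalization). Its modulus measures phase-amplitude
#' coupling strength; its argument is the phase at which the amplitude is
#' largest.
#'
#' @param phase phase series (radians)
#' @param amplitude amplitude series
#' @return complex scalar
#' @export
mvl <- function(phase, amplitude) {
  stopifnot(length(phase) == length(amplitude))
  if (length(phase) == 0) stop("empty input")
  mean(amplitude * exp(1i * phase))
}

#' Phase-locking value
#'
#' Modulus of the time-averaged unit phase-difference vectors; 1 for a
#' constant phase lag, ~`1/sqrt(n)` for independent phases. The mean lag is
#' returned as attribute `"offset"`.
#'
#' @param phase_a,phase_b phase series (radians)
#' @return scalar in \[0, 1\] with attribute `offset`
#' @export
plv <- function(phase_a, phase_b) {
  stopifnot(length(phase_a) == length(phase_b))
  if (length(phase_a) == 0) stop("empty input")
  z <- mean(exp(1i * (phase_a - phase_b)))
  structure(Mod(z), offset = Arg(z))
}

#' Mutual information between two phase series
#'
#' Marginal and joint mass functions estimated with equal-occupancy
#' (equiquantal) binning; MI in nats. Symmetric in its arguments.
#'
#' @param phase_a,phase_b phase series
#' @param n_bins equiquantal bins per margin
#' @return MI >= 0 (nats)
#' @export
phase_mi <- function(phase_a, phase_b, n_bins = 16) {
  stopifnot(length(phase_a) == length(phase_b), n_bins >= 2)
  n <- length(phase_a)
  if (n < 5 * n_bins^2)
    warning("series shorter than 5 bins^2 samples; MI estimate undersampled")
  eq <- function(x) ceiling(rank(x, ties.method = "first") * n_bins / n)
  a <- eq(phase_a); b <- eq(phase_b)
  joint <- table(factor(a, levels = 1:n_bins), factor(b, levels = 1:n_bins))
  pj <- joint / n
  pa <- rowSums(pj); pb <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / outer(pa, pb)[nz]))
}

#' IAAFT surrogates
#'
#' Iterative amplitude-adjusted Fourier-transform surrogates: each
#' surrogate has exactly the original's sorted value distribution, and a
#' power spectrum matched to the original by iterative replacement
#' (stopping after `max_iter` iterations or when the relative spectral
#' change between iterations falls below `tol`).
#'
#' @param signal original series
#' @param n_surrogates number of surrogates
#' @param seed RNG seed
#' @param max_iter iteration cap per surrogate
#' @param tol relative spectral-change stopping tolerance
#' @return matrix `length(signal) x n_surrogates`
#' @export
iaaft_surrogates <- function(signal, n_surrogates, seed = 1,
                             max_iter = 200, tol = 1e-8) {
  n <- length(signal)
  if (sd(signal) < 1e-14) stop("constant signal has no surrogates")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  target_amp <- Mod(fft(signal))
  sorted_vals <- sort(signal)
  out <- matrix(NA_real_, n, n_surrogates)
  for (s in seq_len(n_surrogates)) {
    x <- signal[sample.int(n)]
    prev_rank <- integer(0)
    prev_mismatch <- Inf
    for (it in seq_len(max_iter)) {
      y <- Re(fft(target_amp * exp(1i * Arg(fft(x))), inverse = TRUE) / n)
      rk <- rank(y, ties.method = "first")
      x <- sorted_vals[rk]
      # converged when the rank ordering stops changing (the spectral
      # mismatch is then stationary) or the spectral change drops below tol
      if (identical(rk, prev_rank)) break
      prev_rank <- rk
      if (it %% 10 == 0) {
        mismatch <- sqrt(mean((Mod(fft(x)) - target_amp)^2)) /
          sqrt(mean(target_amp^2))
        if (abs(prev_mismatch - mismatch) < tol) break
        prev_mismatch <- mismatch
      }
    }
    out[, s] <- x
  }
  out
}

#' Surrogate significance test for a cross-frequency coupling statistic
#'
#' Computes the statistic on the original signal pair and on IAAFT
#' surrogates of the spindle-band source signal (the slow-oscillation phase
#' series is kept fixed; band filtering, Hilbert phase/amplitude and the
#' statistic are recomputed per surrogate), yielding an empirical null and
#' the one-sided p-value `(1 + #{null >= value}) / (1 + n_surr)`.
#'
#' @param signal_slow raw series carrying the slow oscillation (e.g.
#'   cortical excitatory rate)
#' @param signal_fast raw series carrying the spindles (e.g. relay rate)
#' @param fs sampling rate (Hz)
#' @param statistic one of `"klmi"`, `"mvl"`, `"plv"`, `"mi"`
#' @param slow_band,fast_band analysis bands (Hz)
#' @param n_surr number of surrogates (>= 20)
#' @param seed RNG seed
#' @param n_bins phase bins (KL-MI) or equiquantal bins (MI)
#' @param surrogate_set optional precomputed [iaaft_surrogates()] matrix of
#'   `signal_fast` (shared across statistics to avoid recomputation)
#' @return object of class `cfc_result`: list with `statistic`, `value`
#'   (scalar; modulus for MVL), `raw` (complex for MVL), `surrogates`,
#'   `p_value`, `n_surr`, bands
#' @examples
#' \donttest{
#' x <- generate_pac_signal(m = 0.9, duration_s = 60, seed = 1)
#' surrogate_test(x, x, fs = 100, statistic = "klmi", n_surr = 200)
#' }
#' @export
surrogate_test <- function(signal_slow, signal_fast, fs,
                           statistic = c("klmi", "mvl", "plv", "mi"),
                           slow_band = c(0.1, 3), fast_band = c(12, 15),
                           n_surr = 1000, seed = 1, n_bins = NULL,
                           surrogate_set = NULL) {
  statistic <- match.arg(statistic)
  if (!is.null(surrogate_set)) n_surr <- ncol(surrogate_set)
  if (n_surr < 20) stop("n_surr < 20 gives too coarse a p-value resolution")
  slow <- band_phase_amplitude(signal_slow, fs, slow_band)
  stat_fun <- switch(statistic,
    klmi = function(fast) kl_mi(slow$phase, fast$amplitude,
                                n_bins = if (is.null(n_bins)) 18 else n_bins),
    mvl = function(fast) mvl(slow$phase, fast$amplitude),
    plv = function(fast) as.numeric(plv(slow$phase, fast$phase)),
    mi = function(fast) phase_mi(slow$phase, fast$phase,
                                 n_bins = if (is.null(n_bins)) 16 else n_bins))
  orig_fast <- band_phase_amplitude(signal_fast, fs, fast_band)
  raw <- stat_fun(orig_fast)
  value <- if (is.complex(raw)) Mod(raw) else as.numeric(raw)
  surr <- if (is.null(surrogate_set))
    iaaft_surrogates(signal_fast, n_surr, seed = seed) else surrogate_set
  null <- vapply(seq_len(n_surr), function(s) {
    fa <- band_phase_amplitude(surr[, s], fs, fast_band)
    v <- stat_fun(fa)
    if (is.complex(v)) Mod(v) else as.numeric(v)
  }, numeric(1))
  p <- (1 + sum(null >= value)) / (1 + n_surr)
  structure(list(statistic = statistic, value = value, raw = raw,
                 surrogates = null, p_value = p, n_surr = n_surr,
                 slow_band = slow_band, fast_band = fast_band),
            class = "cfc_result")
}

#' All cross-frequency coupling statistics against one surrogate null
#'
#' Computes KL-MI, MVL, PLV and MI between the slow-oscillation phase of
#' `signal_slow` and the spindle-band amplitude/phase of `signal_fast`,
#' sharing a single IAAFT surrogate set of `signal_fast` (band filtering
#' and Hilbert transform are performed once per surrogate and reused by all
#' statistics).
#'
#' @inheritParams surrogate_test
#' @param statistics statistics to compute
#' @param klmi_bins,mi_bins bin counts for KL-MI and MI
#' @return named list of `cfc_result` objects
#' @export
cfc_suite <- function(signal_slow, signal_fast, fs,
                      statistics = c("klmi", "mvl", "plv", "mi"),
                      slow_band = c(0.1, 3), fast_band = c(12, 15),
                      n_surr = 1000, seed = 1, klmi_bins = 18,
                      mi_bins = 16) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  if (n_surr < 20) stop("n_surr < 20 gives too coarse a p-value resolution")
  slow <- band_phase_amplitude(signal_slow, fs, slow_band)
  fns <- list(
    klmi = function(fa) kl_mi(slow$phase, fa$amplitude, n_bins = klmi_bins),
    mvl = function(fa) mvl(slow$phase, fa$amplitude),
    plv = function(fa) as.numeric(plv(slow$phase, fa$phase)),
    mi = function(fa) phase_mi(slow$phase, fa$phase, n_bins = mi_bins))
  fns <- fns[statistics]
  orig <- band_phase_amplitude(signal_fast, fs, fast_band)
  raw <- lapply(fns, function(f) f(orig))
  value <- vapply(raw, function(v) if (is.complex(v)) Mod(v) else as.numeric(v),
                  numeric(1))
  surr <- iaaft_surrogates(signal_fast, n_surr, seed = seed)
  null <- matrix(NA_real_, n_surr, length(fns),
                 dimnames = list(NULL, names(fns)))
  for (s in seq_len(n_surr)) {
    fa <- band_phase_amplitude(surr[, s], fs, fast_band)
    null[s, ] <- vapply(fns, function(f) {
      v <- f(fa); if (is.complex(v)) Mod(v) else as.numeric(v)
    }, numeric(1))
  }
  out <- lapply(seq_along(fns), function(j) {
    structure(list(statistic = names(fns)[j], value = value[j],
                   raw = raw[[j]], surrogates = null[, j],
                   p_value = (1 + sum(null[, j] >= value[j])) / (1 + n_surr),
                   n_surr = n_surr, slow_band = slow_band,
                   fast_band = fast_band), class = "cfc_result")
  })
  names(out) <- names(fns)
  out
}

#' @export
print.cfc_result <- function(x, ...) {
  cat(sprintf("<cfc_result> %s = %.4g, p = %.4g (%d surrogates)\n",
              toupper(x$statistic), x$value, x$p_value, x$n_surr))
  invisible(x)
}
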