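# Shared signal-processing helpers: zero-phase FIR bandpass, analytic
# signal, Welch spectra. Filtering follows the common practice for sleep
# EEG pipelines: linear-phase (Hamming) FIR, applied in one pass with the
# group delay compensated, transition bands of a quarter of the band edge
# (at least 2 Hz, never wider than the edge itself), reflection padding.

fir_bandpass_kernel <- function(band, fs, max_len = NULL) {
  lo <- band[1]; hi <- band[2]
  stopifnot(lo > 0, hi > lo, hi < fs / 2)
  # transition width: a quarter of the band edge, at least 2 Hz, never
  # wider than the edge itself nor than half the passband (so that narrow
  # bands keep a flat passband core)
  trans <- function(f) min(max(f * 0.25, 2), f, (hi - lo) / 2)
  width <- min(trans(lo), trans(hi))
  n <- ceiling(3.3 / width * fs)
  if (!is.null(max_len)) n <- min(n, max_len)
  if (n %% 2 == 1) n <- n + 1  # even order -> odd length, integer delay
  k <- signal::fir1(n, c(lo, hi) / (fs / 2), type = "pass")
  # normalize the gain at the band centre to one (the windowed design has
  # a small passband bias for narrow bands)
  fc <- (lo + hi) / 2
  gain <- Mod(sum(k * exp(-2i * pi * fc / fs * seq_along(k))))
  k / gain
}

filtfilt_fir <- function(x, kernel) {
  n <- length(x)
  half <- (length(kernel) - 1) / 2
  pad <- min(half, n - 1)
  xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
  y <- stats::convolve(xp, rev(kernel), type = "open")
  y[(half + pad + 1):(half + pad + n)]
}

#' Zero-phase FIR bandpass filter
#'
#' Linear-phase Hamming-window FIR applied in a single pass with the group
#' delay compensated (zero-phase, non-causal); edges are reflection-padded.
#' The filter length follows from a transition width of a quarter of each
#' band edge (minimum 2 Hz), capped at a third of the signal length.
#'
#' @param x numeric signal
#' @param fs sampling rate (Hz)
#' @param band `c(low, high)` in Hz, inside (0, fs/2)
#' @return filtered signal, same length as `x`
#' @export
fir_bandpass <- function(x, fs, band) {
  if (length(x) < 16) stop("signal too short to filter")
  kernel <- fir_bandpass_kernel(band, fs, max_len = floor(length(x) / 3) * 2)
  filtfilt_fir(x, kernel)
}

#' Analytic signal via the Hilbert transform
#'
#' @param x real signal
#' @return complex vector `x + i * H(x)`
#' @export
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Welch power spectral density
#'
#' Hann-windowed segments with 50% overlap, one-sided density scaling (the
#' integral of the PSD over frequency approximates the signal variance).
#'
#' @param x signal
#' @param fs sampling rate (Hz)
#' @param window_s segment length in seconds
#' @return list with `freq` (Hz) and `psd` (power per Hz)
#' @export
welch_psd <- function(x, fs, window_s = 4) {
  n <- length(x)
  L <- min(round(window_s * fs), n)
  if (L < 8) stop("signal shorter than one analysis window")
  step <- max(1, floor(L / 2))
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1))  # Hann
  starts <- seq(1, n - L + 1, by = step)
  scale <- 1 / (fs * sum(w^2))
  acc <- numeric(floor(L / 2) + 1)
  for (s in starts) {
    seg <- x[s:(s + L - 1)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(fft(seg))^2 * scale
    half <- P[1:(floor(L / 2) + 1)]
    if (L %% 2 == 0) {
      half[2:(L / 2)] <- 2 * half[2:(L / 2)]
    } else {
      half[2:length(half)] <- 2 * half[2:length(half)]
    }
    acc <- acc + half
  }
  list(freq = seq(0, floor(L / 2)) * fs / L, psd = acc / length(starts))
}

#' Dominant frequency of a signal
#'
#' Frequency of maximum Welch spectral power, optionally restricted to a
#' band. Returns `NA` for (near-)constant signals.
#'
#' @param x signal
#' @param fs sampling rate (Hz)
#' @param band optional `c(low, high)` restriction in Hz
#' @param window_s Welch segment length (s)
#' @param min_amplitude peak-to-peak amplitude below which the signal is
#'   treated as a fixed point
#' @return frequency in Hz, or `NA`
#' @export
dominant_frequency <- function(x, fs, band = NULL, window_s = 4,
                               min_amplitude = 0.1) {
  if (diff(range(x)) < min_amplitude) return(NA_real_)
  sp <- welch_psd(x, fs, window_s)
  keep <- sp$freq > 0
  if (!is.null(band)) keep <- keep & sp$freq >= band[1] & sp$freq <= band[2]
  if (!any(keep)) return(NA_real_)
  sp$freq[keep][which.max(sp$psd[keep])]
}
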