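# Noise generators shared by the synthetic-data module.

#' Band-limited Gaussian noise
#'
#' White Gaussian noise filtered with a 4th-order Butterworth band-pass and
#' rescaled to unit standard deviation, so multiplying by an amplitude gives a
#' process whose in-band RMS equals that amplitude.
#'
#' @param n samples.
#' @param fs sampling rate (Hz).
#' @param lo,hi band edges (Hz); `hi` is clipped below Nyquist.
#' @return numeric vector of length `n`, sd = 1.
#' @export
band_limited_noise <- function(n, fs, lo, hi) {
  stopifnot(n > 0, fs > 0, lo >= 0, hi > lo)
  hi <- min(hi, 0.999 * fs / 2)
  w <- c(lo, hi) / (fs / 2)
  bf <- signal::butter(4, w, type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  s <- stats::sd(x)
  if (s == 0) return(x)
  x / s
}

#' 1/f ("pink") Gaussian background noise
#'
#' Spectrally shaped Gaussian noise with power spectral density proportional
#' to 1/f^exponent between `lo` and `hi` Hz and zero outside, rescaled to unit
#' standard deviation. Shaping is done in the frequency domain on white noise.
#'
#' @param n samples.
#' @param fs sampling rate (Hz).
#' @param lo,hi support of the spectrum (Hz).
#' @param exponent spectral exponent (1 = classic pink, the EEG default).
#' @return numeric vector of length `n`, sd = 1.
#' @export
one_over_f_noise <- function(n, fs, lo = 0.5, hi = 100, exponent = 1) {
  stopifnot(n > 1, fs > 0, lo > 0, hi > lo)
  hi <- min(hi, fs / 2)
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  freqs <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  freqs <- pmin(freqs, fs - freqs)           # two-sided frequency axis
  amp <- numeric(n)
  inband <- freqs >= lo & freqs <= hi
  amp[inband] <- freqs[inband]^(-exponent / 2)
  y <- Re(stats::fft(X * amp, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) return(y)
  y / s
}

# Robust signal scale: scaled median absolute deviation (Gaussian-consistent).
robust_scale <- function(x) stats::mad(x, constant = 1.4826)
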