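# Welch power spectral density and absolute band power. Density scaling is
# such that integrating the one-sided PSD over frequency recovers the signal
# variance (Parseval, up to taper loss handled by the window normalization).

#' Default EEG frequency bands
#'
#' Delta 0.5-4 Hz and theta 5-9 Hz (note the deliberate 4-5 Hz gap between
#' them), alpha 9-12, beta 12-30, gamma 30-100 Hz.
#'
#' @return data.frame with columns `name`, `lo_hz`, `hi_hz`.
#' @export
default_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    lo_hz = c(0.5, 5, 9, 12, 30),
    hi_hz = c(4, 9, 12, 30, 100)
  )
}

#' Welch PSD of a numeric series
#'
#' Hann-tapered segments of `window_len_s` seconds with fractional overlap
#' `overlap_frac`; per-segment periodograms are averaged. Segments whose RMS
#' exceeds `artifact_rms_factor` times the median segment RMS are treated as
#' artifacts and dropped from the average (count reported in the result).
#'
#' @param x numeric series (mean is removed before estimation).
#' @param fs sampling rate (Hz).
#' @param window_len_s segment length (s); frequency resolution is its
#'   reciprocal.
#' @param overlap_frac overlap between consecutive segments, in [0, 1).
#' @param artifact_rms_factor RMS outlier factor for segment rejection; Inf
#'   disables rejection.
#' @return An object of class `power_spectrum`: list with `freqs_hz`, `psd`
#'   (uV^2/Hz), `window_len_s`, `overlap_frac`, `n_segments_averaged`,
#'   `n_segments_excluded`.
#' @export
welch_psd <- function(x, fs, window_len_s = 2, overlap_frac = 0.5,
                      artifact_rms_factor = 6) {
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop("overlap_frac must be in [0, 1)")
  L <- round(window_len_s * fs)
  if (L < 2 || L > length(x))
    stop("window longer than signal (need >= ", L, " samples, have ",
         length(x), ")")
  x <- x - mean(x)
  step <- max(1, round(L * (1 - overlap_frac)))
  starts <- seq(1, length(x) - L + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))   # Hann taper
  U <- sum(w^2)
  seg <- vapply(starts, function(s) x[s:(s + L - 1)], numeric(L))
  rms <- sqrt(colMeans(seg^2))
  med <- stats::median(rms)
  keep <- if (is.finite(artifact_rms_factor) && med > 0)
    rms <= artifact_rms_factor * med else rep(TRUE, length(starts))
  if (!any(keep)) keep <- rep(TRUE, length(starts))
  seg <- seg[, keep, drop = FALSE]
  spec <- Mod(stats::mvfft(seg * w))^2 / (fs * U)
  nf <- floor(L / 2) + 1
  psd <- rowMeans(spec[seq_len(nf), , drop = FALSE])
  # one-sided: double everything except DC (and Nyquist when L is even)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (L %% 2 == 0) dbl[nf] <- 1
  psd <- psd * dbl
  structure(list(
    freqs_hz = (seq_len(nf) - 1) * fs / L, psd = psd,
    window_len_s = L / fs, overlap_frac = overlap_frac,
    n_segments_averaged = sum(keep),
    n_segments_excluded = sum(!keep)
  ), class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf(
    "<power_spectrum> %d bins, 0-%.1f Hz @ %.3g Hz, %d segments averaged (%d excluded)\n",
    length(x$freqs_hz), max(x$freqs_hz), x$freqs_hz[2] - x$freqs_hz[1],
    x$n_segments_averaged, x$n_segments_excluded
  ))
  invisible(x)
}

#' Welch PSD of a recording's EEG channel
#'
#' @param recording a [signal_recording()].
#' @inheritParams welch_psd
#' @return A `power_spectrum` (see [welch_psd()]).
#' @export
compute_psd <- function(recording, window_len_s = 2, overlap_frac = 0.5,
                        artifact_rms_factor = 6) {
  stopifnot(inherits(recording, "signal_recording"))
  welch_psd(recording$eeg, recording$eeg_rate_hz, window_len_s, overlap_frac,
            artifact_rms_factor)
}

# trapezoidal integral of the PSD over [lo, hi], interpolating the edges
trapz_band <- function(freqs, psd, lo, hi) {
  if (lo < min(freqs) - 1e-9 || hi > max(freqs) + 1e-9)
    stop(sprintf("band [%g, %g] outside spectrum support [%g, %g]",
                 lo, hi, min(freqs), max(freqs)))
  inside <- freqs > lo & freqs < hi
  f <- c(lo, freqs[inside], hi)
  p <- c(stats::approx(freqs, psd, lo)$y, psd[inside],
         stats::approx(freqs, psd, hi)$y)
  sum(diff(f) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

#' Absolute band power from a power spectrum
#'
#' Absolute power per band is the trapezoidal integral of the PSD over
#' [lo_hz, hi_hz]; adjacent bands sharing an edge each receive half of the
#' shared bin, so disjoint bands never double count. A `relative` column
#' (fraction of total 0-Nyquist power) is included as a derived quantity.
#'
#' @param spectrum a `power_spectrum`.
#' @param bands data.frame with `name`, `lo_hz`, `hi_hz`; defaults to
#'   [default_bands()].
#' @param subject_id optional id carried into the output rows.
#' @return data.frame with columns `subject_id`, `band`, `lo_hz`, `hi_hz`,
#'   `power_uV2`, `relative`.
#' @export
band_power <- function(spectrum, bands = default_bands(),
                       subject_id = NA_character_) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  if (any(bands$lo_hz < 0) || any(bands$lo_hz >= bands$hi_hz))
    stop("bands need 0 <= lo_hz < hi_hz")
  total <- trapz_band(spectrum$freqs_hz, spectrum$psd,
                      min(spectrum$freqs_hz), max(spectrum$freqs_hz))
  pw <- mapply(function(lo, hi) trapz_band(spectrum$freqs_hz, spectrum$psd,
                                           lo, hi),
               bands$lo_hz, bands$hi_hz)
  data.frame(
    subject_id = subject_id, band = bands$name,
    lo_hz = bands$lo_hz, hi_hz = bands$hi_hz,
    power_uV2 = as.numeric(pw),
    relative = if (total > 0) as.numeric(pw) / total else NA_real_
  )
}

#' PSDs over consecutive chunks of a recording
#'
#' Splits the EEG into consecutive non-overlapping chunks of `chunk_len_s`
#' seconds and estimates a Welch PSD for each, e.g. to track band power over
#' a multi-day recording.
#'
#' @param recording a [signal_recording()].
#' @param chunk_len_s chunk length (s), at most the recording duration.
#' @inheritParams welch_psd
#' @return list of `power_spectrum`, one per complete chunk.
#' @export
longitudinal_psd <- function(recording, chunk_len_s, window_len_s = 2,
                             overlap_frac = 0.5, artifact_rms_factor = 6) {
  stopifnot(inherits(recording, "signal_recording"))
  if (chunk_len_s > recording$duration_s + 1e-9)
    stop("chunk_len_s exceeds recording duration")
  fs <- recording$eeg_rate_hz
  n_chunk <- floor(recording$duration_s / chunk_len_s)
  L <- round(chunk_len_s * fs)
  lapply(seq_len(n_chunk), function(i) {
    welch_psd(recording$eeg[((i - 1) * L + 1):(i * L)], fs, window_len_s,
              overlap_frac, artifact_rms_factor)
  })
}
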