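#' Analytic Gabor (Morlet) wavelet coefficients at one frequency
#'
#' FFT implementation of the continuous wavelet transform with a
#' Gaussian-windowed complex exponential. The transfer function is
#' `2 * exp(-(f - f0)^2 * sigma_t^2 * (2*pi^2))` on positive frequencies and
#' zero on negative ones, with `sigma_t = cycles / (2*pi*f0)`, so the
#' magnitude of the output approximates the instantaneous amplitude of a
#' narrowband component at `f0` (a unit-amplitude sinusoid at `f0` maps to
#' magnitude 1).
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param f0 center frequency (Hz).
#' @param cycles number of cycles in the Gaussian envelope (time-frequency
#'   trade-off; larger = better frequency resolution).
#' @return complex vector of wavelet coefficients, same length as `x`.
#' @export
gabor_coefficients <- function(x, fs, f0, cycles = 5) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1L) / n * fs
  # frequencies above Nyquist represent negative frequencies
  pos <- f <= fs / 2
  sigma_t <- cycles / (2 * pi * f0)
  H <- numeric(n)
  H[pos] <- 2 * exp(-2 * pi^2 * sigma_t^2 * (f[pos] - f0)^2)
  stats::fft(X * H, inverse = TRUE) / n
}

#' Gabor wavelet spectrogram
#'
#' Time-frequency decomposition over a frequency grid using the analytic
#' Gabor wavelet. Optionally applies AR(1) whitening first (the stored
#' magnitudes are then of the whitened signal).
#'
#' @param x numeric vector (uV).
#' @param fs sampling rate (Hz).
#' @param freqs strictly increasing frequency grid (Hz); defaults to 53
#'   log-spaced points over 1-100 Hz.
#' @param cycles wavelet cycles.
#' @param whiten apply AR(1) whitening before the transform.
#' @param time_downsample keep every k-th time point of the magnitude matrix
#'   (the transform itself always runs at full rate).
#' @return object of class `wavelet_spectrogram` with fields `magnitude`
#'   (freq x time), `freqs`, `times`, `params`.
#' @export
gabor_spectrogram <- function(x, fs, freqs = NULL, cycles = 5,
                              whiten = FALSE, time_downsample = 1L) {
  if (is.null(freqs))
    freqs <- exp(seq(log(1), log(100), length.out = 53L))
  if (length(freqs) < 1L) stop("empty frequency grid")
  if (any(diff(freqs) <= 0)) stop("freqs must be strictly increasing")
  if (max(freqs) >= fs / 2)
    stop("max frequency ", max(freqs), " Hz is at or above Nyquist")
  if (whiten) x <- whiten_ar1(x)
  keep <- seq(1L, length(x), by = as.integer(time_downsample))
  mag <- matrix(0, length(freqs), length(keep))
  for (i in seq_along(freqs)) {
    mag[i, ] <- Mod(gabor_coefficients(x, fs, freqs[i], cycles))[keep]
  }
  structure(
    list(magnitude = mag, freqs = freqs, times = (keep - 1L) / fs,
         params = list(cycles = cycles, whiten = whiten, fs = fs)),
    class = "wavelet_spectrogram"
  )
}

#' @export
print.wavelet_spectrogram <- function(x, ...) {
  cat("<wavelet_spectrogram> ", length(x$freqs), " freqs (",
      signif(min(x$freqs), 3), "-", signif(max(x$freqs), 3), " Hz) x ",
      length(x$times), " time points\n", sep = "")
  invisible(x)
}

#' Mean wavelet band power time series
#'
#' Average squared wavelet magnitude over a set of frequencies spanning a
#' band; used to build the band-power inputs of the spindle detector without
#' materialising a full spectrogram.
#'
#' @param x numeric vector (uV).
#' @param fs sampling rate (Hz).
#' @param band numeric length-2, band edges in Hz.
#' @param n_freqs number of log-spaced frequencies sampled inside the band.
#' @param cycles wavelet cycles.
#' @return numeric vector of band power (uV^2), same length as `x`.
#' @export
wavelet_band_power <- function(x, fs, band, n_freqs = 6L, cycles = 5) {
  fgrid <- exp(seq(log(band[1L]), log(band[2L]), length.out = n_freqs))
  fgrid <- fgrid[fgrid < fs / 2]
  if (!length(fgrid)) stop("band entirely above Nyquist")
  acc <- numeric(length(x))
  for (f0 in fgrid) acc <- acc + Mod(gabor_coefficients(x, fs, f0, cycles))^2
  acc / length(fgrid)
}
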