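#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth applied forward and backward (`signal::filtfilt`),
#' giving zero group delay. Corner frequencies are clipped just below
#' Nyquist when necessary.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param low,high band edges (Hz); `low = 0` gives a low-pass, `high >=
#'   fs/2` a high-pass.
#' @param order filter order (per pass).
#' @return filtered vector, same length.
#' @export
bandpass_filter <- function(x, fs, low, high, order = 4L) {
  nyq <- fs / 2
  high <- min(high, nyq * 0.999)
  if (low <= 0) {
    bf <- signal::butter(order, high / nyq, type = "low")
  } else if (high >= nyq * 0.999 && low > 0) {
    bf <- signal::butter(order, low / nyq, type = "high")
  } else {
    bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  }
  as.numeric(signal::filtfilt(bf, x))
}

#' Zero-phase high-pass filter
#' @inheritParams bandpass_filter
#' @param cutoff cutoff frequency (Hz).
#' @export
highpass_filter <- function(x, fs, cutoff, order = 4L) {
  bf <- signal::butter(order, cutoff / (fs / 2), type = "high")
  as.numeric(signal::filtfilt(bf, x))
}

#' Apply a zero-phase notch filter to a recording or vector
#'
#' A second-order Butterworth band-stop around `freq` applied with
#' `filtfilt`, used to remove line noise (60 Hz in the clinical recordings
#' this pipeline targets). Attenuation at the notch frequency exceeds 20 dB.
#'
#' @param x a `recording` or numeric vector.
#' @param freq notch center frequency (Hz); must be below Nyquist.
#' @param fs sampling rate, required when `x` is a vector.
#' @param bandwidth full stop-band width (Hz).
#' @return same type as `x`.
#' @export
apply_notch <- function(x, freq, fs = NULL, bandwidth = 4) {
  if (inherits(x, "recording")) {
    fs <- x$fs
    x$signal <- t(apply(x$signal, 1L, apply_notch, freq = freq, fs = fs,
                        bandwidth = bandwidth))
    return(x)
  }
  if (is.null(fs)) stop("`fs` required for vector input")
  if (freq >= fs / 2)
    stop("notch frequency ", freq, " Hz is at or above Nyquist (", fs / 2,
         " Hz)")
  edges <- c(freq - bandwidth / 2, freq + bandwidth / 2) / (fs / 2)
  bf <- signal::butter(2L, edges, type = "stop")
  as.numeric(signal::filtfilt(bf, x))
}

#' Analytic signal via FFT
#'
#' Returns the complex analytic signal (Hilbert transform in the imaginary
#' part): negative frequencies zeroed, positive doubled.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1; h[2L:(n / 2)] <- 2
  } else {
    h[1L] <- 1; h[2L:((n + 1L) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Band-limited Hilbert envelope
#' @inheritParams bandpass_filter
#' @return instantaneous amplitude (uV) of the band-passed signal.
#' @export
hilbert_envelope <- function(x, fs, low, high) {
  Mod(analytic_signal(bandpass_filter(x, fs, low, high)))
}

#' Band-limited instantaneous phase
#' @inheritParams bandpass_filter
#' @return phase in (-pi, pi]; 0 at the band-passed peak (cosine convention).
#' @export
hilbert_phase <- function(x, fs, low, high) {
  Arg(analytic_signal(bandpass_filter(x, fs, low, high)))
}

#' Integer-factor decimation with anti-alias filtering
#' @param x numeric vector.
#' @param factor integer decimation factor.
#' @return decimated vector.
#' @export
decimate_signal <- function(x, factor) {
  factor <- as.integer(factor)
  if (factor <= 1L) return(x)
  as.numeric(signal::decimate(x, factor))
}

# centered moving average (edge-padded), used for envelope smoothing
moving_average <- function(x, n) {
  n <- max(1L, as.integer(n))
  if (n == 1L) return(x)
  xp <- c(rep(x[1L], n), x, rep(x[length(x)], n))
  cs <- cumsum(xp)
  half <- n %/% 2L
  i <- seq_along(x) + n
  (cs[i + (n - half - 1L)] - cs[i - half - 1L]) / n
}

# centered moving RMS
moving_rms <- function(x, n) sqrt(moving_average(x^2, n))

# Gaussian smoothing with sd in samples (FFT-free, truncated kernel)
gaussian_smooth <- function(x, sd_samples) {
  if (sd_samples <= 0) return(x)
  half <- max(1L, ceiling(3 * sd_samples))
  k <- stats::dnorm(seq(-half, half), sd = sd_samples)
  k <- k / sum(k)
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, k, sides = 2L))[(half + 1L):(half + length(x))]
}
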