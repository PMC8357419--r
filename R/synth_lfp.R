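#' 1/f^beta background noise
#'
#' White Gaussian noise spectrally shaped in the frequency domain so the
#' power spectrum follows `1/f^beta`, then rescaled to a target RMS.
#' Emulates the aperiodic background of LFP/EEG.
#'
#' @param n number of samples.
#' @param fs sampling rate (Hz).
#' @param beta power-law exponent (power ~ 1/f^beta).
#' @param rms target root-mean-square amplitude (uV).
#' @return numeric vector of length `n`.
#' @export
pink_noise <- function(n, fs, beta = 1.5, rms = 25) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- (seq_len(n) - 1L) / n * fs
  f[f > fs / 2] <- fs - f[f > fs / 2]    # fold to |f|
  scale <- c(0, f[-1L]^(-beta / 2))      # kill DC
  x <- Re(stats::fft(W * scale, inverse = TRUE) / n)
  x / stats::sd(x) * rms
}

#' Specification for a synthetic LFP/EEG recording
#'
#' Describes a multichannel recording of pink-noise background with injected
#' spindle-band events, optional amplitude-coupled gamma bursts, and optional
#' trace-alternant-like discontinuity. Defaults mirror neonatal rodent LFP:
#' 1250 Hz sampling, 1/f^1.5 background, events of 10-20 Hz lasting
#' 0.5-2 s at 5x the background RMS.
#'
#' @param n_channels number of channels.
#' @param fs sampling rate (Hz).
#' @param duration recording length (s).
#' @param beta background spectral exponent.
#' @param background_rms background RMS (uV).
#' @param events optional data.frame of events (`start_s`, `duration_s`,
#'   `freq_hz`, `amplitude_uV`, `asymmetry`; missing columns filled from the
#'   defaults below). When `NULL`, `n_events` events are placed at random.
#' @param n_events number of random events when `events` is `NULL`.
#' @param event_freq_range event center-frequency range (Hz).
#' @param event_duration_range event duration range (s).
#' @param event_amplitude peak event amplitude (uV); default 5x background.
#' @param asymmetry waveform skew parameter a >= 0: amplitude of a second
#'   harmonic phased to sharpen peaks and blunt troughs
#'   (`sin(phi) - a*cos(2*phi)`, peak-normalised). 0 = symmetric sinusoid;
#'   the peak/trough sharpness ratio grows monotonically with a over
#'   \[0, 0.2\]; beyond a = 0.25 the trough flattens and splits.
#' @param footprint integer channel indices carrying the events (default all).
#' @param gamma_coupling add a gamma carrier whose envelope is shared with
#'   the spindle events.
#' @param gamma_freq gamma carrier frequency (Hz).
#' @param gamma_coef envelope-sharing coefficient in \[0, 1\]: fraction of the
#'   gamma envelope taken from the event envelope.
#' @param gamma_amplitude gamma carrier amplitude (uV).
#' @param discontinuity fraction of (event-free) 1-s segments attenuated to
#'   5% amplitude, emulating discontinuous neonatal activity.
#' @param min_gap minimum gap between consecutive events on a channel (s).
#' @return list of class `synth_lfp_spec`.
#' @export
synth_lfp_spec <- function(n_channels = 4L, fs = 1250, duration = 60,
                           beta = 1.5, background_rms = 25,
                           events = NULL, n_events = 20L,
                           event_freq_range = c(10, 20),
                           event_duration_range = c(0.5, 2),
                           event_amplitude = 5 * background_rms,
                           asymmetry = 0, footprint = NULL,
                           gamma_coupling = FALSE, gamma_freq = 50,
                           gamma_coef = 0.8,
                           gamma_amplitude = 0.4 * background_rms,
                           discontinuity = 0, min_gap = 1.0) {
  if (is.null(footprint)) footprint <- seq_len(n_channels)
  stopifnot(all(footprint >= 1L), all(footprint <= n_channels),
            event_amplitude > 0, asymmetry >= 0,
            gamma_coef >= 0, gamma_coef <= 1,
            discontinuity >= 0, discontinuity < 1)
  structure(as.list(environment()), class = "synth_lfp_spec")
}

# skewed oscillation cycle shape: a second harmonic phased to sharpen the
# peaks and blunt the troughs. a = 0 gives a pure sinusoid; peak-vs-trough
# sharpness asymmetry grows with a up to the trough-flattening point
# a = 0.25 (beyond which the trough splits). Normalised to unit peak.
skewed_wave <- function(phi, a) (sin(phi) - a * cos(2 * phi)) / (1 + a)

#' Generate a synthetic LFP recording with ground truth
#'
#' A pure function of `(spec, seed)`. Events are placed (or taken from the
#' spec), synthesised as amplitude-windowed skewed sinusoids, and added to
#' independent pink-noise backgrounds per channel. The returned ground-truth
#' table lists every injected event per channel.
#'
#' @param spec a [synth_lfp_spec()].
#' @param seed integer random seed.
#' @return list with `recording` (a [recording()]) and `events` (data.frame
#'   `event_id`, `channel`, `start_s`, `end_s`, `freq_hz`, `amplitude_uV`,
#'   `asymmetry`).
#' @export
generate_lfp <- function(spec, seed) {
  stopifnot(inherits(spec, "synth_lfp_spec"))
  set.seed(seed)
  n <- round(spec$duration * spec$fs)
  ev <- spec$events
  if (is.null(ev)) {
    ev <- place_events(spec$n_events, spec$duration,
                       spec$event_duration_range, spec$min_gap)
    if (nrow(ev)) {
      ev$freq_hz <- stats::runif(nrow(ev), spec$event_freq_range[1L],
                                 spec$event_freq_range[2L])
      ev$amplitude_uV <- spec$event_amplitude
      ev$asymmetry <- spec$asymmetry
    }
  } else {
    ev <- as.data.frame(ev)
    if (is.null(ev$duration_s)) ev$duration_s <- ev$end_s - ev$start_s
    if (is.null(ev$freq_hz)) ev$freq_hz <- mean(spec$event_freq_range)
    if (is.null(ev$amplitude_uV)) ev$amplitude_uV <- spec$event_amplitude
    if (is.null(ev$asymmetry)) ev$asymmetry <- spec$asymmetry
  }
  if (nrow(ev)) {
    ev$end_s <- ev$start_s + ev$duration_s
    if (any(ev$start_s < 0) || any(ev$end_s > spec$duration))
      stop("event outside recording")
    o <- order(ev$start_s)
    if (any(ev$start_s[o][-1L] < ev$end_s[o][-nrow(ev)]))
      stop("overlapping events on one channel: ground truth would be ambiguous")
  }
  sig <- matrix(0, spec$n_channels, n)
  for (ch in seq_len(spec$n_channels)) {
    sig[ch, ] <- pink_noise(n, spec$fs, spec$beta, spec$background_rms)
  }
  tvec <- (seq_len(n) - 1L) / spec$fs
  event_env <- numeric(n)                   # shared envelope for gamma coupling
  ev$phi0 <- if (nrow(ev)) stats::runif(nrow(ev), 0, 2 * pi) else numeric(0)
  for (k in seq_len(nrow(ev))) {
    i0 <- round(ev$start_s[k] * spec$fs) + 1L
    i1 <- min(round(ev$end_s[k] * spec$fs), n)
    idx <- i0:i1
    tt <- tvec[idx] - tvec[i0]
    env <- tukey_window(length(idx), 0.2)
    wave <- ev$amplitude_uV[k] * env *
      skewed_wave(2 * pi * ev$freq_hz[k] * tt + ev$phi0[k], ev$asymmetry[k])
    for (ch in spec$footprint) sig[ch, idx] <- sig[ch, idx] + wave
    event_env[idx] <- pmax(event_env[idx], env)
  }
  if (spec$gamma_coupling) {
    own <- abs(gaussian_smooth(stats::rnorm(n), spec$fs * 0.2))
    own <- own / max(stats::sd(own), 1e-12) * 0.5
    genv <- spec$gamma_coef * event_env + (1 - spec$gamma_coef) * own
    carrier <- cos(2 * pi * spec$gamma_freq * tvec +
                     stats::runif(1, 0, 2 * pi))
    for (ch in spec$footprint)
      sig[ch, ] <- sig[ch, ] + spec$gamma_amplitude * genv * carrier
  }
  if (spec$discontinuity > 0) {
    seg <- as.integer(spec$fs)               # 1-s segments
    n_seg <- n %/% seg
    free <- vapply(seq_len(n_seg), function(s) {
      s0 <- (s - 1) / 1; s1 <- s0 + 1
      !any(ev$start_s < s1 & ev$end_s > s0)
    }, logical(1))
    pick <- sample(which(free),
                   size = min(sum(free), round(spec$discontinuity * n_seg)))
    for (s in pick) {
      idx <- ((s - 1L) * seg + 1L):(s * seg)
      sig[, idx] <- sig[, idx] * 0.05
    }
  }
  gt <- if (nrow(ev)) {
    do.call(rbind, lapply(spec$footprint, function(ch) {
      data.frame(event_id = seq_len(nrow(ev)), channel = ch,
                 start_s = ev$start_s, end_s = ev$end_s,
                 freq_hz = ev$freq_hz, amplitude_uV = ev$amplitude_uV,
                 asymmetry = ev$asymmetry, phi0 = ev$phi0)
    }))
  } else {
    data.frame(event_id = integer(0), channel = integer(0),
               start_s = numeric(0), end_s = numeric(0),
               freq_hz = numeric(0), amplitude_uV = numeric(0),
               asymmetry = numeric(0), phi0 = numeric(0))
  }
  rec <- recording(sig, spec$fs,
                   subject_meta = list(species = "synthetic", id = paste0("synth-seed", seed)))
  list(recording = rec, events = gt)
}

# non-overlapping random event placement with a minimum gap and edge margin
place_events <- function(n_events, duration, dur_range, min_gap,
                         margin = 0.5) {
  if (n_events == 0L)
    return(data.frame(start_s = numeric(0), duration_s = numeric(0)))
  durs <- stats::runif(n_events, dur_range[1L], dur_range[2L])
  slack <- duration - 2 * margin - sum(durs) - (n_events - 1L) * min_gap
  if (slack < 0)
    stop("recording too short for ", n_events, " non-overlapping events")
  cuts <- sort(stats::runif(n_events))
  extra <- diff(c(0, cuts)) * slack
  starts <- margin + cumsum(extra) +
    c(0, cumsum(durs[-n_events] + min_gap))
  data.frame(start_s = starts, duration_s = durs)
}

# Tukey (tapered cosine) window, ramp fraction `alpha/2` each side
tukey_window <- function(n, alpha = 0.2) {
  if (n == 1L) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  ramp <- alpha / 2
  lo <- t < ramp
  hi <- t > 1 - ramp
  w[lo] <- 0.5 * (1 + cos(pi * (t[lo] / ramp - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * ((t[hi] - 1 + ramp) / ramp)))
  w
}
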