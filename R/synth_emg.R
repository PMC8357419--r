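#' Bout plan for synthetic EMG
#'
#' Declares wake bouts and twitch times on an atonia background. Wake bouts
#' must not overlap, and twitches (being active-sleep phenomena) must not
#' fall inside wake bouts.
#'
#' @param duration total duration (s).
#' @param wake data.frame with `start_s`, `end_s` of wake bouts (may be
#'   empty).
#' @param twitches numeric vector of twitch center times (s).
#' @param twitch_duration twitch burst duration (s); must be < 1.5 s so the
#'   bursts score as twitches rather than wake.
#' @return list of class `emg_bout_plan`.
#' @export
emg_bout_plan <- function(duration, wake = NULL, twitches = numeric(0),
                          twitch_duration = 0.3) {
  if (is.null(wake))
    wake <- data.frame(start_s = numeric(0), end_s = numeric(0))
  wake <- as.data.frame(wake)
  stopifnot(twitch_duration > 0, twitch_duration < 1.5)
  if (nrow(wake)) {
    o <- order(wake$start_s)
    wake <- wake[o, , drop = FALSE]
    if (any(wake$start_s < 0) || any(wake$end_s > duration))
      stop("wake bout outside recording")
    if (nrow(wake) > 1L && any(wake$start_s[-1L] < wake$end_s[-nrow(wake)]))
      stop("overlapping wake bouts")
  }
  for (tw in twitches) {
    if (tw - twitch_duration / 2 < 0 || tw + twitch_duration / 2 > duration)
      stop("twitch at ", tw, " s extends outside the recording")
    if (nrow(wake) && any(tw >= wake$start_s & tw < wake$end_s))
      stop("twitch at ", tw, " s falls inside a wake bout")
  }
  structure(list(duration = duration, wake = wake, twitches = sort(twitches),
                 twitch_duration = twitch_duration),
            class = "emg_bout_plan")
}

#' Generate a synthetic EMG trace from a bout plan
#'
#' Broadband high-frequency noise (content above the 300 Hz high-pass used
#' by the envelope stage) whose amplitude follows the plan: low during
#' atonia, `wake_factor` times higher during wake bouts (50 ms ramps), and
#' briefly elevated by `twitch_factor` during each twitch.
#'
#' @param plan an [emg_bout_plan()].
#' @param fs sampling rate (Hz); must exceed 600 Hz.
#' @param atonia_rms atonia-background RMS (uV).
#' @param wake_factor amplitude multiplier during wake.
#' @param twitch_factor amplitude multiplier during twitches.
#' @param seed integer random seed.
#' @return list with `emg` (numeric vector, uV), `fs`, and `truth` (the
#'   plan, with twitch intervals expanded).
#' @export
generate_emg <- function(plan, fs = 2000, atonia_rms = 5, wake_factor = 8,
                         twitch_factor = 10, seed = 1L) {
  stopifnot(inherits(plan, "emg_bout_plan"))
  if (fs <= 600) stop("fs must exceed 600 Hz for 300 Hz high-pass content")
  set.seed(seed)
  n <- round(plan$duration * fs)
  carrier <- bandpass_filter(stats::rnorm(n), fs, 300, 0.45 * fs)
  carrier <- carrier / stats::sd(carrier)
  amp <- rep(atonia_rms, n)
  ramp <- round(0.05 * fs)
  set_bout <- function(amp, s0, s1, value) {
    i0 <- max(1L, round(s0 * fs) + 1L); i1 <- min(n, round(s1 * fs))
    amp[i0:i1] <- value
    amp
  }
  for (k in seq_len(nrow(plan$wake)))
    amp <- set_bout(amp, plan$wake$start_s[k], plan$wake$end_s[k],
                    atonia_rms * wake_factor)
  for (tw in plan$twitches)
    amp <- set_bout(amp, tw - plan$twitch_duration / 2,
                    tw + plan$twitch_duration / 2,
                    atonia_rms * twitch_factor)
  amp <- moving_average(amp, ramp)
  truth <- plan
  truth$twitch_intervals <- if (length(plan$twitches)) {
    data.frame(start_s = plan$twitches - plan$twitch_duration / 2,
               end_s = plan$twitches + plan$twitch_duration / 2)
  } else {
    data.frame(start_s = numeric(0), end_s = numeric(0))
  }
  list(emg = carrier * amp, fs = fs, truth = truth)
}
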