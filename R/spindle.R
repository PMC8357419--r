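#' Wavelet band powers for spindle detection
#'
#' Computes the three band-power time series entering the power-asymmetry
#' ratio: spindle band (8-25 Hz), low band (1-5 Hz for rodents and term
#' humans, 2-6 Hz for humans younger than 40 post-gestational weeks), and
#' high band (30-80 Hz). Powers are mean squared Gabor-wavelet magnitudes
#' over log-spaced frequencies inside each band, lightly smoothed in time.
#'
#' @param x numeric vector (uV).
#' @param fs sampling rate (Hz); >= 200.
#' @param variant `"rodent"`, `"human"` (term or older), or
#'   `"human_preterm"` (< 40 weeks; low band 2-6 Hz).
#' @param smooth_s smoothing of each power series (s).
#' @param cycles wavelet cycles; detection uses 4 (shorter than the
#'   5-cycle spectrogram default) so that event boundaries are not blurred
#'   by the wavelet's temporal footprint while keeping cross-band leakage
#'   small (a pure in-band tone still reaches PAR ~0.98).
#' @return list of class `band_power_set`: `Pspi`, `Plow`, `Phigh`,
#'   `fs_power`, `bands`.
#' @export
band_powers <- function(x, fs, variant = c("rodent", "human",
                                           "human_preterm"),
                        smooth_s = 0.05, cycles = 4) {
  variant <- match.arg(variant)
  if (fs < 200) stop("fs must be >= 200 Hz")
  low_band <- if (variant == "human_preterm") c(2, 6) else c(1, 5)
  bands <- list(spindle = c(8, 25), low = low_band, high = c(30, 80))
  sm <- function(p) if (smooth_s > 0) moving_average(p, round(smooth_s * fs)) else p
  structure(list(
    Pspi = sm(wavelet_band_power(x, fs, bands$spindle, n_freqs = 8L,
                                 cycles = cycles)),
    Plow = sm(wavelet_band_power(x, fs, bands$low, n_freqs = 4L,
                                 cycles = cycles)),
    Phigh = sm(wavelet_band_power(x, fs, bands$high, n_freqs = 6L,
                                  cycles = cycles)),
    fs_power = fs, bands = bands
  ), class = "band_power_set")
}

#' Power-asymmetry ratio (PAR)
#'
#' The detection statistic for spindle-band oscillations:
#' `PAR = (Pspi - (Plow + Phigh)) / (Pspi + Plow + Phigh)`, computed
#' pointwise from the wavelet band powers. PAR lies in \[-1, 1\] and
#' approaches +1 when spindle-band power dominates both flanking bands.
#'
#' @inheritParams band_powers
#' @param bands optionally a precomputed [band_powers()] result.
#' @return list of class `par_series`: `par` (NaN where the total power is
#'   zero, with attribute `degenerate` flagging an all-zero input), `bands`
#'   (the `band_power_set`), `fs`.
#' @export
compute_par <- function(x, fs, variant = "rodent", bands = NULL, ...) {
  if (is.null(bands)) bands <- band_powers(x, fs, variant, ...)
  tot <- bands$Pspi + bands$Plow + bands$Phigh
  par <- ifelse(tot > 0,
                (bands$Pspi - (bands$Plow + bands$Phigh)) / tot, NaN)
  degenerate <- all(!is.finite(par))
  structure(list(par = par, bands = bands, fs = bands$fs_power,
                 degenerate = degenerate),
            class = "par_series")
}

#' Detect spindle-band oscillation events
#'
#' Candidate events are runs where PAR exceeds -0.1, restricted to the sleep
#' mask. A run is kept when (i) its duration is between 0.3 and 5 s,
#' (ii) PAR reaches above 0 inside the run, and (iii) spindle-band power
#' inside the run exceeds a threshold of `mad_multiplier` MAD-scaled units
#' above the median spindle-band power within the sleep intervals, with the
#' MAD-derived scale `median(|Pspi|)/0.6745`. Event boundaries are the full
#' PAR run. Both PAR and the threshold scale with the signal, so detections
#' are invariant to amplitude rescaling of the whole recording.
#'
#' @param par_obj a [compute_par()] result.
#' @param mask data.frame of sleep intervals (`start_s`, `end_s`); detection
#'   and the power threshold are restricted to these.
#' @param par_threshold PAR crossing threshold.
#' @param min_dur,max_dur event duration limits (s).
#' @param mad_multiplier power threshold in MAD units above the median.
#' @param channel channel id stored on the events.
#' @return data.frame of events: `channel`, `start_s`, `end_s`,
#'   `start_sample`, `end_sample` (0-based, half-open), `duration_s`,
#'   `peak_par`.
#' @export
detect_spindle_events <- function(par_obj, mask, par_threshold = -0.1,
                                  min_dur = 0.3, max_dur = 5,
                                  mad_multiplier = 3, channel = 1L) {
  stopifnot(inherits(par_obj, "par_series"))
  if (is.null(mask) || !nrow(mask)) stop("empty sleep mask")
  fs <- par_obj$fs
  n <- length(par_obj$par)
  in_mask <- logical(n)
  tvec <- (seq_len(n) - 1L) / fs
  for (k in seq_len(nrow(mask)))
    in_mask <- in_mask | (tvec >= mask$start_s[k] & tvec < mask$end_s[k])
  if (!any(in_mask)) stop("sleep mask does not intersect the recording")
  Pspi <- par_obj$bands$Pspi
  med <- stats::median(Pspi[in_mask])
  mad_scale <- stats::median(abs(Pspi[in_mask])) / 0.6745
  pow_thresh <- med + mad_multiplier * mad_scale
  above <- !is.na(par_obj$par) & par_obj$par > par_threshold & in_mask
  runs <- runs_above(above)
  keep <- logical(nrow(runs))
  peak_par <- numeric(nrow(runs))
  for (k in seq_len(nrow(runs))) {
    idx <- runs$start[k]:runs$end[k]
    dur <- length(idx) / fs
    peak_par[k] <- max(par_obj$par[idx])
    keep[k] <- dur >= min_dur && dur <= max_dur && peak_par[k] > 0 &&
      max(Pspi[idx]) > pow_thresh
  }
  runs <- runs[keep, , drop = FALSE]
  out <- data.frame(
    channel = rep(channel, nrow(runs)),
    start_s = (runs$start - 1L) / fs,
    end_s = runs$end / fs,
    start_sample = runs$start - 1L,
    end_sample = runs$end,
    peak_par = peak_par[keep]
  )
  out$duration_s <- out$end_s - out$start_s
  attr(out, "power_threshold") <- pow_thresh
  out
}

#' Spindle event power
#'
#' Median of the Hilbert envelope of the 8-25 Hz band-passed signal over the
#' event interval, in uV.
#'
#' @param x raw signal (uV).
#' @param fs sampling rate (Hz).
#' @param start_s,end_s event interval (half-open, s).
#' @param band band-pass edges (Hz).
#' @return power in uV.
#' @export
event_power <- function(x, fs, start_s, end_s, band = c(8, 25)) {
  if (end_s <= start_s) stop("empty interval")
  if (end_s - start_s < 1 / band[1L])
    stop("interval shorter than one cycle of the band lower edge; ",
         "filter transient would dominate")
  if (start_s < 0 || end_s > length(x) / fs) stop("interval outside record")
  env <- hilbert_envelope(x, fs, band[1L], band[2L])
  idx <- (floor(start_s * fs) + 1L):ceiling(end_s * fs)
  stats::median(env[idx])
}

#' Spatial extent of a spindle event
#'
#' Fraction of functional channels expressing a co-occurring event with the
#' reference event: co-occurrence requires interval intersection longer than
#' 300 ms and midpoint separation of at most 50 ms. The reference channel
#' counts in the numerator.
#'
#' @param ref_event one-row data.frame (or list) with `start_s`, `end_s` on
#'   the reference channel.
#' @param events_by_channel list (indexed by channel) of event data.frames.
#' @param ref_channel reference channel index.
#' @param n_functional number of functional channels (denominator).
#' @param functional logical vector marking functional channels, used to
#'   validate the reference; default all functional.
#' @param min_overlap minimum intersection (s).
#' @param max_mid_sep maximum midpoint separation (s).
#' @return extent fraction in (0, 1].
#' @export
spatial_extent <- function(ref_event, events_by_channel, ref_channel,
                           n_functional,
                           functional = rep(TRUE, length(events_by_channel)),
                           min_overlap = 0.3, max_mid_sep = 0.05) {
  if (n_functional < 1L) stop("n_functional must be >= 1")
  if (!functional[ref_channel]) stop("reference channel is not functional")
  ref_mid <- (ref_event$start_s + ref_event$end_s) / 2
  count <- 1L                                   # the reference itself
  for (ch in seq_along(events_by_channel)) {
    if (ch == ref_channel || !functional[ch]) next
    ev <- events_by_channel[[ch]]
    if (is.null(ev) || !nrow(ev)) next
    ov <- pmin(ev$end_s, ref_event$end_s) - pmax(ev$start_s, ref_event$start_s)
    mids <- (ev$start_s + ev$end_s) / 2
    if (any(ov > min_overlap & abs(mids - ref_mid) <= max_mid_sep))
      count <- count + 1L
  }
  count / n_functional
}

#' Waveform sharpness asymmetry (extrema mean sharpness ratio, ESR)
#'
#' The raw signal over the event is broadly band-passed at 5-30 Hz to locate
#' zero-crossings; each peak is the raw-data maximum between a rising and
#' the next falling zero-crossing, each trough the raw-data minimum between
#' a falling and the next rising zero-crossing. Sharpness of an extremum is
#' the mean voltage drop to the samples `offset_s` before and after it;
#' ESR = mean peak sharpness / mean trough sharpness. Values away from 1
#' indicate an asymmetric (skewed) waveform.
#'
#' @param x raw signal (uV).
#' @param fs sampling rate (Hz).
#' @param start_s,end_s event interval (s); defaults to the whole signal.
#' @param offset_s sharpness offset (s); the 8 ms convention.
#' @param band broad band-pass for zero-crossing detection (Hz).
#' @return list of class `asymmetry_result`: `sharp_peak`, `sharp_trough`
#'   (uV), `esr`, `n_peaks`, `n_troughs`.
#' @export
waveform_asymmetry <- function(x, fs, start_s = 0, end_s = length(x) / fs,
                               offset_s = 0.008, band = c(5, 30)) {
  filt <- bandpass_filter(x, fs, band[1L], band[2L])
  i0 <- floor(start_s * fs) + 1L
  i1 <- min(length(x), ceiling(end_s * fs))
  seg_f <- filt[i0:i1]
  seg_r <- x[i0:i1]
  if (stats::sd(seg_r) == 0 ||
      max(abs(seg_f)) < 1e-9 * max(max(abs(seg_r)), 1))
    stop("no zero-crossings in the event interval (no band-limited ",
         "oscillation present)")
  s <- sign(seg_f)
  cross <- which(diff(s >= 0) != 0)             # index before the crossing
  if (length(cross) < 2L) stop("no zero-crossings in the event interval")
  rising <- cross[s[cross] < 0]
  falling <- cross[s[cross] >= 0]
  off <- round(offset_s * fs)
  sharp_at <- function(i) {
    if (i - off < 1L || i + off > length(seg_r)) return(NA_real_)
    c(before = seg_r[i - off], after = seg_r[i + off])
  }
  peaks <- numeric(0); troughs <- numeric(0)
  for (rz in rising) {
    fz <- falling[falling > rz]
    if (!length(fz)) next
    idx <- rz:fz[1L]
    p <- idx[which.max(seg_r[idx])]
    v <- sharp_at(p)
    if (!anyNA(v)) peaks <- c(peaks, mean(seg_r[p] - v))
  }
  for (fz in falling) {
    rz <- rising[rising > fz]
    if (!length(rz)) next
    idx <- fz:rz[1L]
    tr <- idx[which.min(seg_r[idx])]
    v <- sharp_at(tr)
    if (!anyNA(v)) troughs <- c(troughs, mean(v - seg_r[tr]))
  }
  if (!length(peaks) || !length(troughs))
    stop("event contains no complete peak/trough pair")
  structure(list(sharp_peak = mean(peaks), sharp_trough = mean(troughs),
                 esr = mean(peaks) / mean(troughs),
                 n_peaks = length(peaks), n_troughs = length(troughs)),
            class = "asymmetry_result")
}

#' Characterize a table of detected events
#'
#' Convenience wrapper adding Hilbert power and ESR columns to a detection
#' table for one channel.
#'
#' @param events data.frame from [detect_spindle_events()].
#' @param x raw signal of that channel (uV).
#' @param fs sampling rate (Hz).
#' @return `events` with `power_uV` and `esr` columns (NA where an event is
#'   too short to characterize).
#' @export
characterize_events <- function(events, x, fs) {
  events$power_uV <- NA_real_
  events$esr <- NA_real_
  for (k in seq_len(nrow(events))) {
    events$power_uV[k] <- tryCatch(
      event_power(x, fs, events$start_s[k], events$end_s[k]),
      error = function(e) NA_real_)
    events$esr[k] <- tryCatch(
      waveform_asymmetry(x, fs, events$start_s[k], events$end_s[k])$esr,
      error = function(e) NA_real_)
  }
  events
}
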