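#' EMG power envelope and tone threshold
#'
#' High-pass filters the EMG at 300 Hz, rectifies, and smooths with a moving
#' RMS to obtain a muscle-tone envelope. The tone threshold is the mean of
#' the envelope plus a multiple of its SD; the multiplier must lie in the
#' 1.5-3.5 range used for per-recording calibration (override with
#' `allow_any_multiplier` for exploration).
#'
#' The multiplier is calibrated per recording: with `sd_multiplier = NULL`
#' (default) an Otsu-style split of the log envelope into a low-tone and a
#' high-tone class supplies the threshold, whose implied multiplier is then
#' clipped into \[1.5, 3.5\]; a fixed multiplier can be supplied instead.
#'
#' @param emg numeric vector (uV).
#' @param fs sampling rate (Hz); must exceed 600 Hz.
#' @param smooth_win smoothing window (s).
#' @param sd_multiplier threshold multiplier in \[1.5, 3.5\], or `NULL` for
#'   the per-recording automatic choice.
#' @param decimate integer factor by which the envelope is decimated.
#' @param allow_any_multiplier permit multipliers outside \[1.5, 3.5\].
#' @return object of class `emg_envelope`: `envelope` (uV, >= 0), `fs_env`,
#'   `mean_power`, `threshold`, `sd_multiplier`, `degenerate` (TRUE when
#'   the envelope is identically zero).
#' @export
emg_envelope <- function(emg, fs, smooth_win = 0.1, sd_multiplier = NULL,
                         decimate = 10L, allow_any_multiplier = FALSE) {
  if (fs <= 600) stop("fs must exceed 600 Hz to allow the 300 Hz high-pass")
  if (!is.null(sd_multiplier) && !allow_any_multiplier &&
      (sd_multiplier < 1.5 || sd_multiplier > 3.5))
    stop("sd_multiplier must lie in [1.5, 3.5]; set allow_any_multiplier ",
         "to override")
  degenerate <- all(emg == 0)
  env <- if (degenerate) {
    abs(emg)
  } else {
    moving_rms(abs(highpass_filter(emg, fs, 300)), round(smooth_win * fs))
  }
  decimate <- max(1L, as.integer(decimate))
  env <- env[seq(1L, length(env), by = decimate)]
  mean_power <- mean(env)
  sd_env <- stats::sd(env)
  if (is.null(sd_multiplier)) {
    sd_multiplier <- if (degenerate || sd_env == 0) 2.5 else {
      le <- log(env + 1e-12)
      t_otsu <- otsu_threshold(le)
      lo <- le[le <= t_otsu]; hi <- le[le > t_otsu]
      sep <- if (length(hi) > 1L && length(lo) > 1L) {
        (mean(hi) - mean(lo)) /
          sqrt((stats::var(lo) + stats::var(hi)) / 2)
      } else 0
      if (sep >= 3) {
        # clearly bimodal tone distribution: threshold at the Otsu split
        min(max((exp(t_otsu) - mean_power) / sd_env, 1.5), 3.5)
      } else {
        # unimodal (little or no high tone): be conservative
        3.5
      }
    }
  }
  threshold <- mean_power + sd_multiplier * sd_env
  structure(list(envelope = env, fs_env = fs / decimate,
                 mean_power = mean_power, threshold = threshold,
                 sd_multiplier = sd_multiplier, degenerate = degenerate),
            class = "emg_envelope")
}

#' Score behavioral states from the EMG envelope
#'
#' Threshold/duration rules: supra-threshold runs lasting at least 1.5 s are
#' wake; supra-threshold runs shorter than 1.5 s on an atonia background are
#' twitches; sub-threshold runs of at least 2 s are atonia. Atonia runs of
#' at least 10 s containing no twitch are quiet sleep; atonia containing
#' twitches is active sleep. Before the duration rules are applied, brief
#' sub-threshold dips (shorter than `close_gap_s`) inside high-tone periods
#' are closed, so a sustained wake bout with momentary envelope dips scores
#' as one run. Runs failing both duration rules are merged into the
#' flanking state when both flanks agree, otherwise left unlabeled.
#'
#' @param env an [emg_envelope()].
#' @param close_gap_s sub-threshold gaps shorter than this are absorbed
#'   into the surrounding supra-threshold run (s).
#' @param min_twitch_s supra-threshold runs shorter than this are treated
#'   as noise excursions, not twitches (s).
#' @return object of class `state_segments`: `intervals` (data.frame
#'   `start_s`, `end_s`, `label` with labels among `wake`, `atonia`,
#'   `quiet_sleep`, `active_sleep`, `twitch`), and `provenance` (thresholds
#'   used). Twitch rows ride on top of the atonia-derived rows.
#' @export
score_states <- function(env, close_gap_s = 0.3, min_twitch_s = 0.05) {
  stopifnot(inherits(env, "emg_envelope"))
  if (!length(env$envelope)) stop("empty envelope")
  fs <- env$fs_env
  high <- env$envelope > env$threshold
  hruns <- merge_runs(runs_above(high), gap = round(close_gap_s * fs))
  high <- logical(length(high))
  for (k in seq_len(nrow(hruns))) high[hruns$start[k]:hruns$end[k]] <- TRUE
  r <- rle(high)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  dur <- r$lengths / fs
  lab <- rep(NA_character_, length(dur))
  lab[r$values & dur >= 1.5] <- "wake"
  lab[r$values & dur < 1.5 & dur >= min_twitch_s] <- "twitch_cand"
  lab[!r$values & dur >= 2] <- "atonia"
  # runs failing both duration rules: merge into agreeing flanks
  for (k in which(is.na(lab))) {
    left <- if (k > 1L) lab[k - 1L] else NA
    right <- if (k < length(lab)) lab[k + 1L] else NA
    if (!is.na(left) && !is.na(right) && left == right &&
        left %in% c("wake", "atonia")) lab[k] <- left
  }
  seg <- data.frame(start_s = (starts - 1L) / fs, end_s = ends / fs,
                    label = lab)
  # twitch candidates are only twitches on an atonia background; on a wake
  # background they are part of wake
  is_cand <- !is.na(seg$label) & seg$label == "twitch_cand"
  for (k in which(is_cand)) {
    left <- if (k > 1L) seg$label[k - 1L] else NA
    right <- if (k < nrow(seg)) seg$label[k + 1L] else NA
    seg$label[k] <- if ((!is.na(left) && left == "wake") ||
                        (!is.na(right) && right == "wake")) "wake" else "twitch"
  }
  twitches <- seg[!is.na(seg$label) & seg$label == "twitch", , drop = FALSE]
  # twitches ride on an atonia background: for the base segmentation they
  # count as atonia so a twitch does not split its surrounding bout
  base_lab <- seg$label
  base_lab[!is.na(base_lab) & base_lab == "twitch"] <- "atonia"
  base <- seg
  base$label <- base_lab
  base <- base[!is.na(base$label) & base$label %in% c("wake", "atonia"), ,
               drop = FALSE]
  base <- collapse_adjacent(base)
  # classify atonia: cut each atonia bout at its twitches; twitch-free
  # stretches of >= 10 s are quiet sleep, stretches near twitches are
  # active sleep, short twitch-free bouts stay plain atonia
  out_rows <- list()
  for (k in seq_len(nrow(base))) {
    if (base$label[k] != "atonia") {
      out_rows[[length(out_rows) + 1L]] <- base[k, , drop = FALSE]
      next
    }
    tw_in <- twitches[twitches$start_s >= base$start_s[k] &
                        twitches$end_s <= base$end_s[k], , drop = FALSE]
    cuts_s <- c(base$start_s[k], tw_in$end_s)
    cuts_e <- c(tw_in$start_s, base$end_s[k])
    has_tw <- nrow(tw_in) > 0L
    for (j in seq_along(cuts_s)) {
      span <- cuts_e[j] - cuts_s[j]
      if (span <= 0) next
      lab_j <- if (span >= 10) "quiet_sleep"
               else if (has_tw) "active_sleep" else "atonia"
      out_rows[[length(out_rows) + 1L]] <-
        data.frame(start_s = cuts_s[j], end_s = cuts_e[j], label = lab_j)
    }
    # the twitch intervals themselves sit on active sleep
    for (j in seq_len(nrow(tw_in)))
      out_rows[[length(out_rows) + 1L]] <-
        data.frame(start_s = tw_in$start_s[j], end_s = tw_in$end_s[j],
                   label = "active_sleep")
  }
  out <- do.call(rbind, out_rows)
  out <- collapse_adjacent(out[order(out$start_s), , drop = FALSE])
  intervals <- rbind(out, twitches)
  intervals <- intervals[order(intervals$start_s), , drop = FALSE]
  rownames(intervals) <- NULL
  structure(list(intervals = intervals,
                 provenance = list(threshold = env$threshold,
                                   sd_multiplier = env$sd_multiplier,
                                   fs_env = fs)),
            class = "state_segments")
}

# Otsu's method: threshold maximising between-class variance of a 1-D sample
otsu_threshold <- function(x, n_bins = 256L) {
  h <- graphics::hist(x, breaks = n_bins, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  w1 <- 1 - w0
  ok <- w0 > 0 & w1 > 0
  between <- rep(-Inf, length(p))
  between[ok] <- (mu_t * w0[ok] - mu[ok])^2 / (w0[ok] * w1[ok])
  mids[which.max(between)]
}

collapse_adjacent <- function(seg) {
  if (nrow(seg) < 2L) return(seg)
  keep <- rep(TRUE, nrow(seg))
  for (k in 2L:nrow(seg)) {
    if (seg$label[k] == seg$label[k - 1L] &&
        abs(seg$start_s[k] - seg$end_s[k - 1L]) < 1e-9) {
      seg$start_s[k] <- seg$start_s[k - 1L]
      keep[k - 1L] <- FALSE
    }
  }
  # also absorb merged short gaps that were relabeled to the flank state
  out <- seg[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Twitch center times
#'
#' One timestamp per scored twitch: the midpoint of its supra-threshold run.
#'
#' @param segments a `state_segments` object.
#' @return numeric vector of twitch centers (s), possibly empty.
#' @export
twitch_times <- function(segments) {
  stopifnot(inherits(segments, "state_segments"))
  tw <- segments$intervals[segments$intervals$label == "twitch", ,
                           drop = FALSE]
  if (!nrow(tw)) return(numeric(0))
  (tw$start_s + tw$end_s) / 2
}

#' Sleep mask from scored states
#'
#' Intervals of muscle atonia (quiet sleep, active sleep, or unclassified
#' atonia), used to restrict spindle detection to sleep.
#'
#' @param segments a `state_segments` object.
#' @return data.frame with `start_s`, `end_s`.
#' @export
sleep_mask <- function(segments) {
  iv <- segments$intervals
  iv <- iv[iv$label %in% c("atonia", "quiet_sleep", "active_sleep"), ,
           drop = FALSE]
  data.frame(start_s = iv$start_s, end_s = iv$end_s)
}
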