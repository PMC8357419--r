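#' AR(1) parametric whitening
#'
#' Estimates the lag-1 autoregressive coefficient from the data and returns
#' the innovation series `x[t] - phi * x[t-1]` (length `n - 1`). Flattens
#' the 1/f tilt of LFP spectra so that transient oscillations stand out in
#' wavelet spectrograms.
#'
#' @param x numeric vector of length >= 2.
#' @return numeric vector of length `length(x) - 1`, with the estimated
#'   coefficient attached as attribute `phi`.
#' @export
whiten_ar1 <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples")
  if (stats::sd(x) == 0) stop("constant input: AR(1) coefficient undefined")
  x0 <- x - mean(x)
  phi <- sum(x0[-n] * x0[-1L]) / sum(x0[-n]^2)
  out <- x[-1L] - phi * x[-n]
  attr(out, "phi") <- phi
  out
}

#' Detect oscillatory epochs by amplitude thresholding
#'
#' Continuity analysis of the neural signal: the rectified (and lightly
#' smoothed) amplitude is compared with the 99th percentile of the wideband
#' noise floor, estimated from the quietest 1-s windows of the recording
#' (the lowest-RMS decile). Supra-threshold runs are merged across short
#' gaps and short residual runs dropped.
#'
#' @param x numeric vector (uV).
#' @param fs sampling rate (Hz).
#' @param smooth_s smoothing window for the rectified amplitude (s).
#' @param gap_s merge gaps shorter than this (s).
#' @param min_dur_s discard epochs shorter than this (s).
#' @param floor_percentile percentile of the noise-floor amplitude
#'   distribution used as threshold.
#' @return object of class `oscillatory_epochs`: `intervals` (data.frame
#'   `start_s`, `end_s`), `threshold` (uV), `mean_duration_s`,
#'   `total_duration_s`, `wideband_power` (uV^2, mean of `x^2` within
#'   epochs).
#' @export
detect_oscillatory_epochs <- function(x, fs, smooth_s = 0.025, gap_s = 0.1,
                                      min_dur_s = 0.2,
                                      floor_percentile = 0.99) {
  n <- length(x)
  if (n < 10 * fs) stop("need at least 10 s of signal for noise-floor estimation")
  amp <- moving_average(abs(x), round(smooth_s * fs))
  win <- as.integer(fs)            # 1-s windows for the floor estimate
  n_win <- n %/% win
  idx <- rep(seq_len(n_win), each = win)
  rms_w <- sqrt(tapply(x[seq_len(n_win * win)]^2, idx, mean))
  quiet <- which(rms_w <= stats::quantile(rms_w, 0.1, names = FALSE))
  quiet_samples <- unlist(lapply(quiet, function(w)
    ((w - 1L) * win + 1L):(w * win)), use.names = FALSE)
  threshold <- stats::quantile(amp[quiet_samples], floor_percentile,
                               names = FALSE)
  runs <- runs_above(amp > threshold)
  runs <- merge_runs(runs, gap = round(gap_s * fs))
  if (nrow(runs)) runs <- runs[(runs$end - runs$start + 1L) >= min_dur_s * fs, ,
                               drop = FALSE]
  intervals <- data.frame(start_s = (runs$start - 1L) / fs,
                          end_s = runs$end / fs)
  inside <- logical(n)
  for (k in seq_len(nrow(runs))) inside[runs$start[k]:runs$end[k]] <- TRUE
  structure(
    list(intervals = intervals,
         threshold = threshold,
         mean_duration_s = if (nrow(intervals)) mean(intervals$end_s - intervals$start_s) else 0,
         total_duration_s = sum(intervals$end_s - intervals$start_s),
         wideband_power = if (any(inside)) mean(x[inside]^2) else NA_real_),
    class = "oscillatory_epochs"
  )
}

# runs of TRUE in a logical vector -> data.frame(start, end) of sample idx
runs_above <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# merge runs separated by gaps < gap samples
merge_runs <- function(runs, gap) {
  if (nrow(runs) < 2L) return(runs)
  keep_start <- runs$start[1L]
  out_s <- integer(0); out_e <- integer(0)
  cur_e <- runs$end[1L]
  for (k in 2L:nrow(runs)) {
    if (runs$start[k] - cur_e - 1L < gap) {
      cur_e <- runs$end[k]
    } else {
      out_s <- c(out_s, keep_start); out_e <- c(out_e, cur_e)
      keep_start <- runs$start[k]; cur_e <- runs$end[k]
    }
  }
  data.frame(start = c(out_s, keep_start), end = c(out_e, cur_e))
}

#' Twitch-triggered average spectrogram
#'
#' Extracts a window of the wavelet magnitude around each twitch, z-scores
#' each frequency row within the window, zeroes lags temporally coincident
#' with the twitch (to avoid movement-artifact contamination), and averages
#' over twitches.
#'
#' @param spec a `wavelet_spectrogram`.
#' @param twitches twitch center times (s).
#' @param window half-window around the twitch (s).
#' @param zero_window half-width of the coincidence-zeroing window (s).
#' @return list with `z` (freq x lag matrix), `lags` (s), `freqs`,
#'   `n_twitches`.
#' @export
twitch_triggered_spectrogram <- function(spec, twitches, window = 1,
                                         zero_window = 0.05) {
  dt <- diff(spec$times[1:2])
  half <- round(window / dt)
  n_t <- length(spec$times)
  centers <- round(twitches / dt) + 1L
  valid <- centers - half >= 1L & centers + half <= n_t
  centers <- centers[valid]
  if (!length(centers)) stop("no twitch with a full window inside the record")
  acc <- matrix(0, length(spec$freqs), 2L * half + 1L)
  for (c0 in centers) {
    w <- spec$magnitude[, (c0 - half):(c0 + half), drop = FALSE]
    mu <- rowMeans(w)
    sdv <- apply(w, 1L, stats::sd)
    sdv[sdv == 0] <- 1
    acc <- acc + (w - mu) / sdv
  }
  z <- acc / length(centers)
  lags <- seq(-half, half) * dt
  z[, abs(lags) <= zero_window] <- 0
  list(z = z, lags = lags, freqs = spec$freqs, n_twitches = length(centers))
}

#' Cross-correlogram of twitches and detected events with a shuffled null
#'
#' Counts event times relative to each twitch in lag bins, and derives a
#' pointwise 95% confidence band by re-drawing the event times uniformly
#' over the record span `n_shuffle` times.
#'
#' @param twitches twitch times (s).
#' @param events event times (s).
#' @param span record duration (s) over which shuffled events are drawn.
#' @param lag_range maximum absolute lag (s).
#' @param bin bin width (s).
#' @param n_shuffle number of shuffles for the null (must be >= 1).
#' @return list with `lags` (bin centers, s), `counts`, `ci_low`, `ci_high`,
#'   `exceeds` (logical, counts outside the band).
#' @export
twitch_event_xcorr <- function(twitches, events, span, lag_range = 2,
                               bin = 0.1, n_shuffle = 500L) {
  if (!length(twitches) || !length(events)) stop("empty series")
  if (n_shuffle < 1L) stop("n_shuffle must be >= 1")
  breaks <- seq(-lag_range, lag_range, by = bin)
  centers <- breaks[-1L] - bin / 2
  count_lags <- function(ev) {
    d <- outer(ev, twitches, `-`)
    d <- d[abs(d) <= lag_range]
    if (!length(d)) return(numeric(length(centers)))
    as.numeric(table(cut(d, breaks = breaks)))
  }
  counts <- count_lags(events)
  null_counts <- matrix(0, n_shuffle, length(centers))
  for (s in seq_len(n_shuffle)) {
    null_counts[s, ] <- count_lags(stats::runif(length(events), 0, span))
  }
  ci_low <- apply(null_counts, 2L, stats::quantile, probs = 0.025)
  ci_high <- apply(null_counts, 2L, stats::quantile, probs = 0.975)
  list(lags = centers, counts = counts, ci_low = ci_low, ci_high = ci_high,
       exceeds = counts > ci_high | counts < ci_low)
}

#' Aperiodic (1/f) exponent of a power spectrum
#'
#' Robust log-log fit of power versus frequency over a band, with
#' narrowband peaks masked: a first Huber regression flags points whose
#' residuals exceed 2.5 robust SDs, and the fit is repeated without them.
#' The exponent is the negative slope, so a `1/f^2` spectrum gives 2.
#'
#' @param freqs frequency grid (Hz).
#' @param power spectral power at `freqs` (must be positive).
#' @param band fit band (Hz).
#' @return list with `exponent`, `offset` (log10 power at 1 Hz),
#'   `r_squared`, `band`, `n_masked`.
#' @export
aperiodic_exponent <- function(freqs, power, band = c(2, 40)) {
  sel <- freqs >= band[1L] & freqs <= band[2L]
  if (sum(sel) < 10L) stop("need at least 10 frequencies in the fit band")
  if (any(power[sel] <= 0)) stop("non-positive power in the fit band")
  lf <- log10(freqs[sel]); lp <- log10(power[sel])
  fit1 <- MASS::rlm(lp ~ lf, maxit = 50)
  res <- stats::residuals(fit1)
  sc <- stats::mad(res)
  keep <- if (sc > 0) abs(res) <= 2.5 * sc else rep(TRUE, length(res))
  fit2 <- MASS::rlm(lp[keep] ~ lf[keep], maxit = 50)
  pred <- stats::coef(fit2)[1L] + stats::coef(fit2)[2L] * lf[keep]
  ss_res <- sum((lp[keep] - pred)^2)
  ss_tot <- sum((lp[keep] - mean(lp[keep]))^2)
  list(exponent = -unname(stats::coef(fit2)[2L]),
       offset = unname(stats::coef(fit2)[1L]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       band = band, n_masked = sum(!keep))
}
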