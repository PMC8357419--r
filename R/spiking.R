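#' Detect multi-unit spikes on high-band channels
#'
#' Spikes are negative peaks of the 250-2500 Hz band-passed signal
#' exceeding `threshold_mult` times the per-channel noise floor
#' (`median(|x|)/0.6745`). Detections coincident (within `coincidence_s`)
#' across channels farther apart than `artifact_dist_um` are presumed
#' non-physiological and removed from all channels; within a histological
#' zone, detections closer than 2 ms are presumed duplicates of one action
#' potential and only the first is kept.
#'
#' @param highband channels x samples matrix, already band-limited to
#'   250-2500 Hz (uV). Use [bandpass_filter()] on raw data first otherwise.
#' @param fs sampling rate (Hz).
#' @param zones character vector, zone label per channel.
#' @param positions_um numeric vector of channel depths/positions (um);
#'   used for the cross-distance artifact rule.
#' @param threshold_mult threshold in noise-floor multiples.
#' @param dedup_s within-zone duplicate window (s).
#' @param coincidence_s cross-channel coincidence window for artifact
#'   removal (s).
#' @param artifact_dist_um distance above which coincident spikes are
#'   artifacts (um).
#' @return data.frame of class `spike_train`: `time_s` (sorted), `channel`,
#'   `zone`, `amplitude_uV` (negative peak value); per-channel noise floors
#'   as attribute `noise_floor`.
#' @export
detect_spikes <- function(highband, fs, zones, positions_um = NULL,
                          threshold_mult = 4, dedup_s = 0.002,
                          coincidence_s = 5e-4, artifact_dist_um = 300) {
  if (is.vector(highband)) highband <- matrix(highband, nrow = 1L)
  n_ch <- nrow(highband)
  if (length(zones) != n_ch) stop("zones must be assigned for every channel")
  if (anyNA(zones)) stop("zones unassigned for some channels")
  if (is.null(positions_um)) positions_um <- rep(0, n_ch)
  floor_uV <- apply(highband, 1L, function(v) stats::median(abs(v)) / 0.6745)
  det <- list()
  for (ch in seq_len(n_ch)) {
    x <- highband[ch, ]
    thr <- -threshold_mult * floor_uV[ch]
    below <- x < thr
    # local minima within sub-threshold runs
    runs <- runs_above(below)
    if (!nrow(runs)) next
    tt <- numeric(nrow(runs)); aa <- numeric(nrow(runs))
    for (k in seq_len(nrow(runs))) {
      idx <- runs$start[k]:runs$end[k]
      j <- idx[which.min(x[idx])]
      tt[k] <- (j - 1L) / fs
      aa[k] <- x[j]
    }
    det[[ch]] <- data.frame(time_s = tt, channel = ch, zone = zones[ch],
                            amplitude_uV = aa)
  }
  if (!length(det)) {
    out <- data.frame(time_s = numeric(0), channel = integer(0),
                      zone = character(0), amplitude_uV = numeric(0))
    attr(out, "noise_floor") <- floor_uV
    class(out) <- c("spike_train", class(out))
    return(out)
  }
  all_sp <- do.call(rbind, det)
  all_sp <- all_sp[order(all_sp$time_s), , drop = FALSE]
  # cross-distance coincidence artifacts: drop from all channels
  drop <- rep(FALSE, nrow(all_sp))
  if (nrow(all_sp) > 1L) {
    for (i in seq_len(nrow(all_sp) - 1L)) {
      j <- i + 1L
      while (j <= nrow(all_sp) &&
             all_sp$time_s[j] - all_sp$time_s[i] <= coincidence_s) {
        dist <- abs(positions_um[all_sp$channel[i]] -
                      positions_um[all_sp$channel[j]])
        if (dist > artifact_dist_um) drop[c(i, j)] <- TRUE
        j <- j + 1L
      }
    }
  }
  all_sp <- all_sp[!drop, , drop = FALSE]
  # within-zone duplicates: keep the first
  all_sp <- dedup_spikes(all_sp, dedup_s)
  rownames(all_sp) <- NULL
  attr(all_sp, "noise_floor") <- floor_uV
  class(all_sp) <- c("spike_train", class(all_sp))
  all_sp
}

#' Remove within-zone duplicate detections
#'
#' Collapses spikes in the same zone closer than `dedup_s` to the earliest
#' one. Idempotent: applying it twice gives the same train.
#'
#' @param spikes data.frame with `time_s` (sorted) and `zone`.
#' @param dedup_s duplicate window (s).
#' @return filtered data.frame.
#' @export
dedup_spikes <- function(spikes, dedup_s = 0.002) {
  if (nrow(spikes) < 2L) return(spikes)
  keep <- rep(TRUE, nrow(spikes))
  last_time <- list()
  for (i in seq_len(nrow(spikes))) {
    z <- spikes$zone[i]
    lt <- last_time[[z]]
    if (!is.null(lt) && spikes$time_s[i] - lt < dedup_s) {
      keep[i] <- FALSE
    } else {
      last_time[[z]] <- spikes$time_s[i]
    }
  }
  out <- spikes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Inter-spike intervals
#'
#' @param times sorted spike times (s), at least 2.
#' @return numeric vector of `n - 1` positive intervals (s).
#' @export
isi <- function(times) {
  if (length(times) < 2L) stop("need at least 2 spikes")
  diff(sort(times))
}

#' Spike-time autocorrelogram with convolution-based confidence intervals
#'
#' Counts spike-pair lags in bins of `bin_s` over +-`window_s` (zero-lag
#' bin excluded). A smoothed expected count per bin is obtained by
#' convolving the correlogram with a hollow Gaussian kernel (zero central
#' weight, sigma = `kernel_sd_bins` bins); pointwise 95% bands are Poisson
#' quantiles of that expectation. `burst_excess` sums counts above the
#' upper band at lags below 50 ms; `suppression_excess` sums the deficit
#' below the lower band over 50-500 ms.
#'
#' @param times sorted spike times (s); at least `min_spikes`.
#' @param bin_s bin width (s).
#' @param window_s maximum absolute lag (s).
#' @param kernel_sd_bins kernel SD in bins.
#' @param min_spikes minimum spikes required.
#' @return object of class `autocorrelogram`: `lags` (bin centers, s),
#'   `counts`, `expected`, `ci_low`, `ci_high`, `burst_excess`,
#'   `suppression_excess`, `flags` (per-bin -1/0/+1).
#' @export
autocorrelogram_ci <- function(times, bin_s = 0.01, window_s = 0.5,
                               kernel_sd_bins = 2, min_spikes = 50L) {
  times <- sort(times)
  n <- length(times)
  if (n < min_spikes) stop("need at least ", min_spikes, " spikes")
  lags <- spike_pair_lags(times, window_s)
  breaks <- seq(-window_s, window_s, by = bin_s)
  centers <- breaks[-1L] - bin_s / 2
  counts <- as.numeric(table(cut(lags, breaks = breaks)))
  zero_bin <- which(abs(centers) < bin_s / 2)
  counts[zero_bin] <- 0
  # hollow Gaussian expectation
  half <- ceiling(4 * kernel_sd_bins)
  k <- stats::dnorm(seq(-half, half), sd = kernel_sd_bins)
  k[half + 1L] <- 0
  k <- k / sum(k)
  cp <- c(rev(counts[seq_len(half)]), counts,
          rev(counts[(length(counts) - half + 1L):length(counts)]))
  expected <- as.numeric(stats::filter(cp, k, sides = 2L))[
    (half + 1L):(half + length(counts))]
  expected[zero_bin] <- NA
  ci_low <- stats::qpois(0.025, expected)
  ci_high <- stats::qpois(0.975, expected)
  flags <- integer(length(counts))
  ok <- !is.na(expected)
  flags[ok & counts > ci_high] <- 1L
  flags[ok & counts < ci_low] <- -1L
  burst_idx <- ok & abs(centers) < 0.05
  supp_idx <- ok & abs(centers) >= 0.05 & abs(centers) <= 0.5
  structure(list(
    lags = centers, counts = counts, expected = expected,
    ci_low = ci_low, ci_high = ci_high,
    burst_excess = sum(pmax(counts - ci_high, 0)[burst_idx]),
    suppression_excess = sum(pmax(ci_low - counts, 0)[supp_idx]),
    flags = flags
  ), class = "autocorrelogram")
}

# all pairwise lags within +-window (both signs), zero-lag self pairs excluded
spike_pair_lags <- function(times, window_s) {
  n <- length(times)
  out <- vector("list", n)
  j0 <- 1L
  for (i in seq_len(n)) {
    while (times[i] - times[j0] > window_s) j0 <- j0 + 1L
    if (j0 < i) out[[i]] <- times[i] - times[j0:(i - 1L)]
  }
  d <- unlist(out, use.names = FALSE)
  c(d, -d)
}

#' Event-triggered spike rate (normalized PSTH) with shuffled CI
#'
#' Bins spike counts around event onsets and normalizes by the rate in a
#' pre-event baseline window. The 95% band comes from re-drawing the spike
#' times uniformly over the record span `n_shuffle` times.
#'
#' @param times spike times (s).
#' @param events event onset times (s); at least 5.
#' @param span record duration (s).
#' @param bin_s bin width (s).
#' @param window range of lags around the event onset (s).
#' @param baseline baseline window relative to onset (s).
#' @param n_shuffle number of shuffles.
#' @return list with `lags`, `rate` (baseline-normalized; NA with
#'   `undefined = TRUE` when the baseline rate is zero), `ci_low`,
#'   `ci_high` (normalized), `baseline_rate_hz`.
#' @export
event_triggered_rate <- function(times, events, span, bin_s = 0.05,
                                 window = c(-1, 2),
                                 baseline = c(-1.0, -0.2),
                                 n_shuffle = 200L) {
  if (length(events) < 5L) stop("need at least 5 events")
  breaks <- seq(window[1L], window[2L], by = bin_s)
  centers <- breaks[-1L] - bin_s / 2
  psth_counts <- function(tt) {
    d <- unlist(lapply(events, function(e) {
      dd <- tt - e
      dd[dd >= window[1L] & dd <= window[2L]]
    }), use.names = FALSE)
    if (!length(d)) return(numeric(length(centers)))
    as.numeric(table(cut(d, breaks = breaks)))
  }
  base_count <- function(tt) {
    sum(vapply(events, function(e)
      sum(tt - e >= baseline[1L] & tt - e < baseline[2L]), 0))
  }
  counts <- psth_counts(times)
  bc <- base_count(times)
  base_rate <- bc / (length(events) * (baseline[2L] - baseline[1L]))
  undefined <- base_rate == 0
  denom <- base_rate * length(events) * bin_s
  rate <- if (undefined) rep(NA_real_, length(centers)) else counts / denom
  null_rates <- matrix(NA_real_, n_shuffle, length(centers))
  for (s in seq_len(n_shuffle)) {
    tt <- stats::runif(length(times), 0, span)
    nb <- base_count(tt)
    nbr <- nb / (length(events) * (baseline[2L] - baseline[1L]))
    if (nbr > 0)
      null_rates[s, ] <- psth_counts(tt) / (nbr * length(events) * bin_s)
  }
  list(lags = centers, rate = rate,
       ci_low = apply(null_rates, 2L, stats::quantile, 0.025, na.rm = TRUE),
       ci_high = apply(null_rates, 2L, stats::quantile, 0.975, na.rm = TRUE),
       baseline_rate_hz = base_rate, undefined = undefined)
}

# ---- circular statistics -------------------------------------------------

#' Mean resultant length of a sample of angles
#' @param phases angles (rad).
#' @return scalar in \[0, 1\].
#' @export
circ_resultant <- function(phases) {
  Mod(mean(exp(1i * phases)))
}

#' Maximum-likelihood von Mises concentration
#'
#' Inverts the relation `R = I1(kappa)/I0(kappa)` with the standard
#' piecewise approximation of the inverse.
#'
#' @param phases angles (rad).
#' @return kappa estimate (>= 0).
#' @export
vm_kappa <- function(phases) {
  R <- circ_resultant(phases)
  if (R < 0.53) {
    2 * R + R^3 + 5 * R^5 / 6
  } else if (R < 0.85) {
    -0.4 + 1.39 * R + 0.43 / (1 - R)
  } else {
    1 / (R^3 - 4 * R^2 + 3 * R)
  }
}

#' Rayleigh test for circular uniformity
#'
#' @param phases angles (rad).
#' @return list with `r` (resultant length), `z` (`n r^2`), `p` (with the
#'   standard finite-sample correction).
#' @export
rayleigh_test <- function(phases) {
  n <- length(phases)
  R <- circ_resultant(phases)
  z <- n * R^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  list(r = R, z = z, p = max(min(p, 1), 0))
}

#' Kuiper test for circular uniformity
#'
#' Two-sided analogue of the Kolmogorov-Smirnov test on the circle, with
#' the asymptotic tail probability series.
#'
#' @param phases angles (rad).
#' @return list with `V` (test statistic) and `p`.
#' @export
kuiper_test <- function(phases) {
  n <- length(phases)
  u <- sort((phases %% (2 * pi)) / (2 * pi))
  i <- seq_len(n)
  Dp <- max(i / n - u)
  Dm <- max(u - (i - 1) / n)
  V <- Dp + Dm
  lam <- (sqrt(n) + 0.155 + 0.24 / sqrt(n)) * V
  j <- 1:20
  p <- 2 * sum((4 * j^2 * lam^2 - 1) * exp(-2 * j^2 * lam^2))
  list(V = V, p = max(min(p, 1), 0))
}

#' Spindle-phase locking of a spike train
#'
#' The LFP is decimated to ~125 Hz, narrowly band-passed at 9-16 Hz, and
#' the analytic-signal phase extracted (0 = band-passed peak, +-pi =
#' trough). Spikes are restricted to the supplied event intervals; the von
#' Mises concentration is estimated by maximum likelihood, and significance
#' requires `kappa > 0.1` together with circular-uniformity `p < 0.05`
#' (Rayleigh by default, Kuiper via `test`).
#'
#' @param times spike times (s).
#' @param lfp LFP vector (uV).
#' @param fs LFP sampling rate (Hz).
#' @param event_intervals data.frame `start_s`, `end_s`; only spikes inside
#'   these intervals are used.
#' @param band phase band (Hz).
#' @param target_fs decimation target (Hz).
#' @param test `"rayleigh"` or `"kuiper"`.
#' @param min_spikes minimum usable spikes.
#' @return object of class `phase_locking`: `phases`, `kappa`,
#'   `preferred_phase`, `r`, `p`, `significant`, `histogram` (counts in
#'   pi/24 bins), `n_spikes`.
#' @export
phase_locking <- function(times, lfp, fs, event_intervals,
                          band = c(9, 16), target_fs = 125,
                          test = c("rayleigh", "kuiper"), min_spikes = 20L) {
  test <- match.arg(test)
  dec <- max(1L, round(fs / target_fs))
  lfp_d <- decimate_signal(lfp, dec)
  fs_d <- fs / dec
  z <- analytic_signal(bandpass_filter(lfp_d, fs_d, band[1L], band[2L]))
  keep <- rep(FALSE, length(times))
  for (k in seq_len(nrow(event_intervals)))
    keep <- keep | (times >= event_intervals$start_s[k] &
                      times < event_intervals$end_s[k])
  tt <- times[keep]
  if (length(tt) < min_spikes)
    stop("need at least ", min_spikes, " spikes within events, got ",
         length(tt))
  # interpolate the analytic signal at the exact spike times: at ~125 Hz a
  # nearest-sample phase is quantised by ~0.6 rad at spindle frequencies,
  # which would bias the concentration estimate downward
  grid_t <- (seq_along(z) - 1L) / fs_d
  zr <- stats::approx(grid_t, Re(z), xout = tt, rule = 2)$y
  zi <- stats::approx(grid_t, Im(z), xout = tt, rule = 2)$y
  phases <- atan2(zi, zr)
  kappa <- vm_kappa(phases)
  pref <- Arg(mean(exp(1i * phases)))
  pp <- if (test == "rayleigh") rayleigh_test(phases)$p else kuiper_test(phases)$p
  breaks <- seq(-pi, pi, by = pi / 24)
  structure(list(phases = phases, kappa = kappa, preferred_phase = pref,
                 r = circ_resultant(phases), p = pp,
                 significant = kappa > 0.1 && pp < 0.05,
                 histogram = as.numeric(table(cut(phases, breaks = breaks))),
                 n_spikes = length(phases)),
            class = "phase_locking")
}
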