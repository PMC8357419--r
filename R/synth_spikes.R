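#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler. `kappa = 0` gives the circular uniform.
#'
#' @param n number of draws.
#' @param mu preferred direction (rad).
#' @param kappa concentration (>= 0).
#' @return angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      u3 <- stats::runif(1)
      theta <- mu + sign(u3 - 0.5) * acos(f)
      out[i] <- atan2(sin(theta), cos(theta))
      i <- i + 1L
    }
  }
  out
}

#' Specification for synthetic multi-unit spiking
#'
#' @param baseline_rate baseline firing rate (Hz).
#' @param event_gain multiplicative rate factor during spindle-band events.
#' @param kappa von Mises concentration of spike phases relative to the
#'   event oscillation (0 = no phase preference).
#' @param pref_phase preferred phase (rad) in the analytic-signal (cosine)
#'   convention: 0 = band-passed peak, +-pi = trough.
#' @param refractory absolute refractory period (s).
#' @param duplicate_p probability that a spike is echoed on a second channel
#'   of the same zone within 2 ms (exercises duplicate removal).
#' @param zones named integer vector or list mapping channel index -> zone
#'   label (`"superficial"`, `"deep-A"`, `"deep-B"`).
#' @return list of class `synth_spikes_spec`.
#' @export
synth_spikes_spec <- function(baseline_rate = 2, event_gain = 3, kappa = 0,
                              pref_phase = pi, refractory = 0.002,
                              duplicate_p = 0,
                              zones = c(ch1 = "deep-A", ch2 = "deep-A")) {
  stopifnot(baseline_rate >= 0, event_gain >= 0, kappa >= 0,
            refractory >= 0, duplicate_p >= 0, duplicate_p <= 1)
  structure(as.list(environment()), class = "synth_spikes_spec")
}

#' Generate ground-truth spike times
#'
#' Piecewise-homogeneous Poisson process: `baseline_rate` outside events and
#' `baseline_rate * event_gain` inside. When `kappa > 0`, spikes falling
#' inside an event are repositioned so their oscillation phase is a von
#' Mises draw around `pref_phase`; the drawn phase is recorded as ground
#' truth. The phase convention matches [hilbert_phase()]: events synthesised
#' by [generate_lfp()] as `env*sin(2*pi*f*t + phi0)` have analytic phase
#' `2*pi*f*t + phi0 - pi/2`.
#'
#' @param spec a [synth_spikes_spec()].
#' @param duration recording duration (s).
#' @param events optional data.frame of events with `start_s`, `end_s`,
#'   `freq_hz` and (for the phase mapping) `phi0`; when `phi0` is absent the
#'   phase mapping assumes 0.
#' @param seed integer random seed.
#' @return data.frame with `time_s` (sorted), `channel`, `zone`,
#'   `in_event`, `phase` (NA outside events or when `kappa == 0`),
#'   `duplicate` (logical; echoes injected for dedup testing).
#' @export
generate_spikes <- function(spec, duration, events = NULL, seed = 1L) {
  stopifnot(inherits(spec, "synth_spikes_spec"))
  set.seed(seed)
  in_event <- function(t) {
    if (is.null(events) || !nrow(events)) return(rep(FALSE, length(t)))
    out <- rep(FALSE, length(t))
    for (k in seq_len(nrow(events)))
      out <- out | (t >= events$start_s[k] & t < events$end_s[k])
    out
  }
  max_rate <- spec$baseline_rate * max(1, spec$event_gain)
  if (max_rate <= 0) {
    return(data.frame(time_s = numeric(0), channel = integer(0),
                      zone = character(0), in_event = logical(0),
                      phase = numeric(0), duplicate = logical(0)))
  }
  n_cand <- stats::rpois(1L, max_rate * duration)
  t_cand <- sort(stats::runif(n_cand, 0, duration))
  ev_flag <- in_event(t_cand)
  rate <- ifelse(ev_flag, spec$baseline_rate * spec$event_gain,
                 spec$baseline_rate)
  keep <- stats::runif(n_cand) < rate / max_rate
  t_sp <- t_cand[keep]
  ev_flag <- ev_flag[keep]
  phase <- rep(NA_real_, length(t_sp))
  if (spec$kappa > 0 && !is.null(events) && nrow(events) && any(ev_flag)) {
    for (j in which(ev_flag)) {
      k <- which(t_sp[j] >= events$start_s & t_sp[j] < events$end_s)[1L]
      f <- events$freq_hz[k]
      phi0 <- if (!is.null(events$phi0)) events$phi0[k] else 0
      theta <- rvonmises(1L, spec$pref_phase, spec$kappa)
      # analytic phase at time t (cosine convention): 2*pi*f*(t-t0)+phi0-pi/2
      target_arg <- theta + pi / 2 - phi0
      cur_arg <- 2 * pi * f * (t_sp[j] - events$start_s[k])
      kcyc <- round((cur_arg - target_arg) / (2 * pi))
      t_new <- events$start_s[k] + (target_arg + 2 * pi * kcyc) / (2 * pi * f)
      t_new <- min(max(t_new, events$start_s[k]), events$end_s[k] - 1e-6)
      t_sp[j] <- t_new
      phase[j] <- theta
    }
    o <- order(t_sp)
    t_sp <- t_sp[o]; ev_flag <- ev_flag[o]; phase <- phase[o]
  }
  if (spec$refractory > 0 && length(t_sp) > 1L) {
    keep <- c(TRUE, diff(t_sp) >= spec$refractory)
    t_sp <- t_sp[keep]; ev_flag <- ev_flag[keep]; phase <- phase[keep]
  }
  zones <- unlist(spec$zones)
  n_ch <- length(zones)
  ch <- sample.int(n_ch, length(t_sp), replace = TRUE)
  out <- data.frame(time_s = t_sp, channel = ch,
                    zone = unname(zones[ch]), in_event = ev_flag,
                    phase = phase, duplicate = FALSE)
  if (spec$duplicate_p > 0 && n_ch > 1L && nrow(out)) {
    echo <- which(stats::runif(nrow(out)) < spec$duplicate_p)
    if (length(echo)) {
      dup <- out[echo, , drop = FALSE]
      for (j in seq_len(nrow(dup))) {
        same_zone <- setdiff(which(zones == dup$zone[j]), dup$channel[j])
        if (!length(same_zone)) next
        dup$channel[j] <- same_zone[1L]
        dup$time_s[j] <- dup$time_s[j] + stats::runif(1, 1e-4, 2e-3)
        dup$duplicate[j] <- TRUE
      }
      out <- rbind(out, dup[dup$duplicate, , drop = FALSE])
      out <- out[order(out$time_s), , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  out
}

# biphasic extracellular spike template, dominant negative deflection,
# total width ~0.6 ms; normalised so min = -1
spike_template <- function(fs, width_s = 6e-4) {
  half <- round(width_s * fs / 2)
  t <- seq(-half, half) / fs
  sig <- width_s / 5
  w <- -t / sig * exp(-t^2 / (2 * sig^2))   # derivative of Gaussian
  w / abs(min(w))
}

#' Inject spike transients into synthetic high-band channels
#'
#' Builds 250-2500 Hz band-limited noise channels and adds a biphasic spike
#' template (0.6 ms wide, dominant negative peak) at each ground-truth spike
#' time on its channel, scaled to a multiple of the per-channel noise floor
#' (MAD-based, as used by the detector).
#'
#' @param spikes data.frame from [generate_spikes()].
#' @param duration duration (s).
#' @param fs sampling rate (Hz); must be >= 5000 for the 2500 Hz band edge.
#' @param n_channels number of channels.
#' @param noise_rms noise RMS before band-limiting (uV).
#' @param amplitude_factor spike peak as a multiple of the noise floor.
#' @param seed integer random seed.
#' @return list with `highband` (channels x samples matrix, uV), `fs`, and
#'   `noise_floor` (per channel, uV).
#' @export
inject_spike_transients <- function(spikes, duration, fs = 10000,
                                    n_channels = 2L, noise_rms = 5,
                                    amplitude_factor = 8, seed = 1L) {
  if (fs < 5000) stop("fs must be >= 5000 Hz for the 250-2500 Hz band")
  set.seed(seed)
  n <- round(duration * fs)
  hb <- matrix(0, n_channels, n)
  for (ch in seq_len(n_channels))
    hb[ch, ] <- bandpass_filter(stats::rnorm(n, sd = noise_rms), fs, 250, 2500)
  floor_uV <- apply(hb, 1L, function(v) stats::median(abs(v)) / 0.6745)
  tmpl <- spike_template(fs)
  half <- (length(tmpl) - 1L) %/% 2L
  for (j in seq_len(nrow(spikes))) {
    ch <- spikes$channel[j]
    if (ch > n_channels) next
    c0 <- round(spikes$time_s[j] * fs) + 1L
    idx <- (c0 - half):(c0 + half)
    ok <- idx >= 1L & idx <= n
    hb[ch, idx[ok]] <- hb[ch, idx[ok]] +
      amplitude_factor * floor_uV[ch] * tmpl[ok]
  }
  list(highband = hb, fs = fs, noise_floor = floor_uV)
}
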