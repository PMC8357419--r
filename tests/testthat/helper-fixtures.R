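# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files are read.

# single-channel LFP with injected events, used across detection tests
fixture_lfp <- function(seed = 42L, duration = 120, n_events = 20L, ...) {
  spec <- synth_lfp_spec(n_channels = 1L, duration = duration,
                         n_events = n_events, ...)
  generate_lfp(spec, seed)
}

# match detected against true events by maximal overlap; returns, per true
# event, the worst boundary error of its best-overlapping detection (NA if
# none overlaps)
boundary_errors <- function(detected, truth) {
  vapply(seq_len(nrow(truth)), function(k) {
    if (!nrow(detected)) return(NA_real_)
    ov <- pmin(detected$end_s, truth$end_s[k]) -
      pmax(detected$start_s, truth$start_s[k])
    if (max(ov) <= 0) return(NA_real_)
    j <- which.max(ov)
    max(abs(detected$start_s[j] - truth$start_s[k]),
        abs(detected$end_s[j] - truth$end_s[k]))
  }, numeric(1))
}

detection_precision <- function(detected, truth) {
  if (!nrow(detected)) return(NA_real_)
  mean(vapply(seq_len(nrow(detected)), function(j) {
    any(pmin(detected$end_s[j], truth$end_s) -
          pmax(detected$start_s[j], truth$start_s) > 0)
  }, logical(1)))
}

# clean skewed oscillation in noise for ESR tests
fixture_skewed_event <- function(a, fs = 1250, dur = 2, freq = 12,
                                 amplitude = 250, noise_rms = 25,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- (0:(fs * dur - 1)) / fs
  amplitude * (sin(2 * pi * freq * t) - a * cos(2 * pi * 2 * freq * t)) +
    pink_noise(length(t), fs, 1.5, noise_rms)
}
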