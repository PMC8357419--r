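test_that("spike detection recovers injected transients", {
  spec <- synth_spikes_spec(baseline_rate = 20, event_gain = 1,
                            refractory = 0.003,
                            zones = c(ch1 = "deep-A", ch2 = "deep-B"))
  sp <- generate_spikes(spec, duration = 10, seed = 61)
  hb <- inject_spike_transients(sp, 10, fs = 10000, n_channels = 2,
                                amplitude_factor = 8, seed = 62)
  det <- detect_spikes(hb$highband, hb$fs, zones = c("deep-A", "deep-B"))
  err <- vapply(sp$time_s, function(t0) min(abs(det$time_s - t0)), numeric(1))
  expect_gte(mean(err < 1e-3), 0.95)
  prec <- mean(vapply(det$time_s, function(t0)
    min(abs(sp$time_s - t0)) < 1e-3, logical(1)))
  expect_gte(prec, 0.9)
  expect_error(detect_spikes(hb$highband, hb$fs, zones = "deep-A"),
               "every channel")
})

test_that("coincident far-apart detections are removed from all channels", {
  fs <- 10000
  set.seed(63)
  n <- fs * 5
  hb <- rbind(bandpass_filter(rnorm(n, sd = 5), fs, 250, 2500),
              bandpass_filter(rnorm(n, sd = 5), fs, 250, 2500))
  tmpl_amp <- 8 * median(abs(hb[1, ])) / 0.6745
  # same-time artifact on channels 400 um apart
  i0 <- fs * 2
  hb[1, i0] <- hb[1, i0] - tmpl_amp
  hb[2, i0 + 2] <- hb[2, i0 + 2] - tmpl_amp   # within 0.5 ms
  det <- detect_spikes(hb, fs, zones = c("deep-A", "deep-B"),
                       positions_um = c(0, 400))
  expect_false(any(abs(det$time_s - 2) < 0.001))
  # same geometry but channels 200 um apart: both kept (different zones)
  det2 <- detect_spikes(hb, fs, zones = c("deep-A", "deep-B"),
                        positions_um = c(0, 200))
  expect_equal(sum(abs(det2$time_s - 2) < 0.001), 2)
})

test_that("within-zone duplicates keep the first spike and dedup is idempotent", {
  sp <- data.frame(time_s = c(1.000, 1.001, 1.005, 2.000),
                   zone = c("deep-A", "deep-A", "deep-A", "deep-A"))
  d1 <- dedup_spikes(sp, 0.002)
  expect_equal(d1$time_s, c(1.000, 1.005, 2.000))
  expect_identical(dedup_spikes(d1, 0.002), d1)
  # different zones are not deduplicated
  sp2 <- data.frame(time_s = c(1.000, 1.001), zone = c("deep-A", "deep-B"))
  expect_equal(nrow(dedup_spikes(sp2, 0.002)), 2)
})

test_that("ISI matches direct differencing and the exponential mean", {
  expect_equal(isi(c(0.0, 0.1, 0.3)), c(0.1, 0.2))
  expect_error(isi(1.0), "2 spikes")
  set.seed(64)
  tt <- cumsum(rexp(1e4, 20))
  expect_equal(mean(isi(tt)), 1 / 20, tolerance = 0.05 / 20 * 20)
  # event-gain epochs: distribution equals brute-force differencing
  spec <- synth_spikes_spec(baseline_rate = 5, event_gain = 4,
                            zones = c(ch1 = "deep-A"))
  ev <- data.frame(start_s = c(10, 30), end_s = c(15, 35), freq_hz = 12)
  sp <- generate_spikes(spec, 50, events = ev, seed = 65)
  expect_identical(isi(sp$time_s), diff(sort(sp$time_s)))
})

test_that("autocorrelogram CIs are calibrated and detect bursting", {
  # Poisson train: ~5% of bins outside the 95% band
  out_frac <- vapply(1:10, function(s) {
    set.seed(s)
    tt <- cumsum(rexp(1000, 5))
    acg <- autocorrelogram_ci(tt)
    ok <- !is.na(acg$expected)
    mean(acg$flags[ok] != 0)
  }, numeric(1))
  expect_gte(mean(out_frac), 0.02)
  expect_lte(mean(out_frac), 0.08)
  # doublet train: burst excess flagged
  set.seed(66)
  base <- cumsum(rexp(500, 2))
  acg_d <- autocorrelogram_ci(sort(c(base, base + 0.005)))
  expect_gt(acg_d$burst_excess, 0)
  expect_true(any(acg_d$flags[abs(acg_d$lags) < 0.05] == 1))
  # symmetry about zero lag
  set.seed(67)
  tt <- cumsum(rexp(300, 3))
  acg_s <- autocorrelogram_ci(tt, min_spikes = 50)
  expect_equal(acg_s$counts, rev(acg_s$counts))
  expect_error(autocorrelogram_ci(1:10), "50 spikes")
})

test_that("event-triggered rate recovers the generator's gain", {
  spec <- synth_spikes_spec(baseline_rate = 5, event_gain = 3,
                            zones = c(ch1 = "deep-A"))
  ev <- data.frame(start_s = seq(5, 115, by = 6),
                   end_s = seq(5, 115, by = 6) + 1, freq_hz = 12)
  sp <- generate_spikes(spec, 120, events = ev, seed = 68)
  ps <- event_triggered_rate(sp$time_s, ev$start_s, span = 120,
                             n_shuffle = 100)
  inev <- ps$lags > 0.1 & ps$lags < 0.9
  expect_equal(mean(ps$rate[inev]), 3, tolerance = 0.3 / 3 * 3)
  # gain 1: rate within CI nearly everywhere
  spec1 <- synth_spikes_spec(baseline_rate = 5, event_gain = 1,
                             zones = c(ch1 = "deep-A"))
  sp1 <- generate_spikes(spec1, 120, events = ev, seed = 69)
  ps1 <- event_triggered_rate(sp1$time_s, ev$start_s, span = 120,
                              n_shuffle = 100)
  inside <- ps1$rate >= ps1$ci_low & ps1$rate <= ps1$ci_high
  expect_gte(mean(inside), 0.9)
  # zero baseline rate flagged undefined
  ps0 <- event_triggered_rate(c(5.1, 11.2, 17.3, 23.1, 29.5), ev$start_s,
                              span = 120, n_shuffle = 10)
  expect_true(ps0$undefined)
  expect_error(event_triggered_rate(sp$time_s, c(1, 2), span = 120),
               "5 events")
})

test_that("circular statistics are calibrated", {
  set.seed(70)
  # Rayleigh type-I error at 5% under uniformity
  rej <- mean(vapply(1:500, function(i)
    rayleigh_test(runif(100, -pi, pi))$p < 0.05, logical(1)))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
  # kappa MLE inverts I1/I0
  ph5 <- rvonmises(5000, 0, 5)
  expect_equal(vm_kappa(ph5), 5, tolerance = 0.2 * 5)
  ph0 <- runif(1000, -pi, pi)
  expect_lt(vm_kappa(ph0), 0.15)
  # Kuiper agrees with Rayleigh on a strongly locked sample
  expect_lt(kuiper_test(rvonmises(200, 1, 3))$p, 0.01)
  expect_gt(kuiper_test(runif(500, -pi, pi))$p, 0.05)
})

test_that("phase locking recovers generator kappa and applies thresholds", {
  speck <- synth_spikes_spec(baseline_rate = 3, event_gain = 8, kappa = 5,
                             pref_phase = pi, refractory = 0,
                             zones = c(ch1 = "deep-A"))
  lspec <- synth_lfp_spec(n_channels = 1, duration = 240, n_events = 40,
                          event_freq_range = c(12, 12),
                          event_amplitude = 250)
  g <- generate_lfp(lspec, 21)
  gt <- g$events[g$events$channel == 1, ]
  spk <- generate_spikes(speck, 240, events = gt, seed = 22)
  pl <- phase_locking(spk$time_s, g$recording$signal[1, ], 1250, gt)
  expect_equal(pl$kappa, 5, tolerance = 0.2 * 5)
  expect_equal(pl$preferred_phase, pi, tolerance = 0.15)
  expect_true(pl$significant)
  expect_equal(length(pl$histogram), 48)      # pi/24 bins over 2*pi
  # the significance flag is the conjunction of both thresholds
  expect_identical(pl$significant, pl$kappa > 0.1 && pl$p < 0.05)
  # unlocked spikes over the same events: not significant
  spec0 <- synth_spikes_spec(baseline_rate = 3, event_gain = 8, kappa = 0,
                             zones = c(ch1 = "deep-A"))
  spk0 <- generate_spikes(spec0, 240, events = gt, seed = 23)
  pl0 <- phase_locking(spk0$time_s, g$recording$signal[1, ], 1250, gt)
  expect_lt(pl0$kappa, 0.2)
  expect_false(pl0$significant)
  expect_error(phase_locking(spk$time_s[1:5], g$recording$signal[1, ], 1250,
                             gt), "20 spikes")
})
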