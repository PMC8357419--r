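test_that("PAR matches the closed-form ratio of independent band powers", {
  set.seed(41)
  fs <- 250
  x <- pink_noise(fs * 60, fs, 1.5, 25)
  pr <- compute_par(x, fs)
  # oracle: recompute the three band powers independently and apply the
  # formula pointwise
  b <- band_powers(x, fs, "rodent")
  oracle <- (b$Pspi - (b$Plow + b$Phigh)) / (b$Pspi + b$Plow + b$Phigh)
  expect_lt(max(abs(pr$par - oracle)), 1e-9)
  expect_true(all(pr$par >= -1 & pr$par <= 1))
  # pure 15 Hz tone: PAR near +1
  tone <- sin(2 * pi * 15 * (0:(fs * 20 - 1)) / fs)
  expect_gt(median(compute_par(tone, fs)$par), 0.9)
  # equal powers give zero by construction of the formula
  expect_equal((3 - (1 + 2)) / (3 + 1 + 2), 0)
  # all-zero signal flagged
  expect_true(compute_par(numeric(fs * 10), fs)$degenerate)
})

test_that("human preterm variant shifts the low band to 2-6 Hz", {
  set.seed(42)
  fs <- 250
  x <- pink_noise(fs * 30, fs, 1.5, 25)
  b_r <- band_powers(x, fs, "rodent")
  b_h <- band_powers(x, fs, "human_preterm")
  expect_equal(b_r$bands$low, c(1, 5))
  expect_equal(b_h$bands$low, c(2, 6))
  expect_false(isTRUE(all.equal(b_r$Plow, b_h$Plow)))
})

test_that("duration and peak rules gate candidate PAR runs", {
  fs <- 250
  dur <- 20
  mask <- data.frame(start_s = 0, end_s = dur)
  # synthetic PAR series: a single supra-threshold run of chosen length
  mk_par <- function(run_s, peak = 0.8) {
    n <- dur * fs
    par <- rep(-0.5, n)
    Pspi <- rep(1, n)
    i <- (5 * fs):(5 * fs + round(run_s * fs) - 1)
    par[i] <- peak
    Pspi[i] <- 100
    structure(list(par = par,
                   bands = list(Pspi = Pspi, fs_power = fs),
                   fs = fs, degenerate = FALSE), class = "par_series")
  }
  expect_equal(nrow(detect_spindle_events(mk_par(0.2), mask)), 0)
  expect_equal(nrow(detect_spindle_events(mk_par(6), mask)), 0)
  expect_equal(nrow(detect_spindle_events(mk_par(1.0), mask)), 1)
  # run with PAR peak below zero is rejected even at valid duration
  expect_equal(nrow(detect_spindle_events(mk_par(1.0, peak = -0.05),
                                          mask)), 0)
  ev <- detect_spindle_events(mk_par(1.0), mask)
  expect_equal(ev$duration_s, 1.0, tolerance = 0.01)
  expect_error(detect_spindle_events(
    compute_par(pink_noise(fs * 20, fs), fs),
    data.frame(start_s = numeric(0), end_s = numeric(0))), "mask")
})

test_that("injected events are recovered with tight boundaries", {
  g <- fixture_lfp(seed = 42, duration = 120, n_events = 20)
  x <- g$recording$signal[1, ]
  fs <- g$recording$fs
  ev <- detect_spindle_events(compute_par(x, fs),
                              data.frame(start_s = 0, end_s = 120))
  truth <- g$events[g$events$channel == 1, ]
  err <- boundary_errors(ev, truth)
  expect_gte(mean(!is.na(err)), 0.9)                    # recall
  expect_gte(detection_precision(ev, truth), 0.9)       # precision
  expect_lt(mean(err, na.rm = TRUE), 0.1)               # boundaries
  # detections never overlap and stay inside the mask
  o <- order(ev$start_s)
  expect_true(all(ev$start_s[o][-1] >= ev$end_s[o][-nrow(ev)]))
})

test_that("detection is invariant to amplitude rescaling", {
  g <- fixture_lfp(seed = 44, duration = 60, n_events = 8)
  x <- g$recording$signal[1, ]
  fs <- g$recording$fs
  mask <- data.frame(start_s = 0, end_s = 60)
  e1 <- detect_spindle_events(compute_par(x, fs), mask)
  e2 <- detect_spindle_events(compute_par(x * 7.3, fs), mask)
  expect_equal(e1$start_s, e2$start_s)
  expect_equal(e1$end_s, e2$end_s)
})

test_that("event power equals the Hilbert envelope median", {
  fs <- 1250
  t <- (0:(fs * 4 - 1)) / fs
  # constant-amplitude 15 Hz sinusoid: power = amplitude
  x <- 80 * sin(2 * pi * 15 * t)
  expect_equal(event_power(x, fs, 0.5, 3.5), 80, tolerance = 0.02 * 80)
  # linearity (filtfilt edge-condition handling is linear only to ~1e-5)
  expect_equal(event_power(3 * x, fs, 0.5, 3.5),
               3 * event_power(x, fs, 0.5, 3.5), tolerance = 1e-4)
  # ramped amplitude: equals the sample median of the envelope (oracle)
  ramp <- seq(10, 90, length.out = length(t)) * sin(2 * pi * 12 * t)
  env <- Mod(analytic_signal(bandpass_filter(ramp, fs, 8, 25)))
  idx <- (floor(0.5 * fs) + 1):ceiling(3.5 * fs)
  expect_equal(event_power(ramp, fs, 0.5, 3.5), median(env[idx]),
               tolerance = 1e-12)
  expect_error(event_power(x, fs, 1, 1.05), "cycle")
  expect_error(event_power(x, fs, 3, 5), "outside")
})

test_that("spatial extent applies the overlap and midpoint rules", {
  ref <- data.frame(start_s = 10, end_s = 11)
  mk <- function(s, e) data.frame(start_s = s, end_s = e)
  # identical event on all 10 channels
  evs <- c(list(mk(10, 11)), rep(list(mk(10, 11)), 9))
  expect_equal(spatial_extent(ref, evs, 1, 10), 1.0)
  # midpoint offset 60 ms: not counted
  evs2 <- list(mk(10, 11), mk(10.06, 11.06))
  expect_equal(spatial_extent(ref, evs2, 1, 2), 0.5)
  # midpoint offset 40 ms: counted
  evs3 <- list(mk(10, 11), mk(10.04, 11.04))
  expect_equal(spatial_extent(ref, evs3, 1, 2), 1.0)
  # overlap 250 ms with aligned midpoints: not counted
  evs4 <- list(mk(10, 11), mk(10.375, 10.625))
  expect_equal(spatial_extent(ref, evs4, 1, 2), 0.5)
  expect_error(spatial_extent(ref, evs4, 2, 2,
                              functional = c(TRUE, FALSE)),
               "not functional")
})

test_that("ESR is 1 for sinusoids, inverts under sign flip, and tracks skew", {
  fs <- 1250
  t <- (0:(fs * 2 - 1)) / fs
  pure <- sin(2 * pi * 12 * t)
  expect_equal(waveform_asymmetry(pure, fs)$esr, 1, tolerance = 0.05)
  skew <- fixture_skewed_event(0.15, seed = 45)
  r <- waveform_asymmetry(skew, fs)
  expect_gt(r$esr, 1)
  r_inv <- waveform_asymmetry(-skew, fs)
  expect_equal(r_inv$esr, 1 / r$esr, tolerance = 1e-6)
  # brute-force oracle: recompute sharpness cycle by cycle from the
  # zero-crossings of the 5-30 Hz filtered trace
  seg_f <- bandpass_filter(skew, fs, 5, 30)
  s <- sign(seg_f)
  cross <- which(diff(s >= 0) != 0)
  rising <- cross[s[cross] < 0]; falling <- cross[s[cross] >= 0]
  off <- round(0.008 * fs)
  pk <- c(); tr <- c()
  for (rz in rising) {
    fz <- falling[falling > rz][1]
    if (is.na(fz)) next
    i <- (rz:fz)[which.max(skew[rz:fz])]
    if (i - off >= 1 && i + off <= length(skew))
      pk <- c(pk, mean(c(skew[i] - skew[i - off], skew[i] - skew[i + off])))
  }
  for (fz in falling) {
    rz <- rising[rising > fz][1]
    if (is.na(rz)) next
    i <- (fz:rz)[which.min(skew[fz:rz])]
    if (i - off >= 1 && i + off <= length(skew))
      tr <- c(tr, mean(c(skew[i - off] - skew[i], skew[i + off] - skew[i])))
  }
  expect_equal(r$esr, mean(pk) / mean(tr), tolerance = 1e-9)
  expect_error(waveform_asymmetry(rep(1, fs), fs), "zero-crossings")
})

test_that("measured ESR increases with the generator's skew parameter", {
  set.seed(46)
  lev <- runif(100)
  esr <- vapply(lev, function(l)
    waveform_asymmetry(fixture_skewed_event(0.2 * l), 1250)$esr, numeric(1))
  expect_gt(cor(lev, esr, method = "spearman"), 0.9)
})
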