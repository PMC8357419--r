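test_that("AR(1) whitening recovers the coefficient and flattens acf", {
  set.seed(31)
  # white noise: phi ~ 0, output ~ input
  w <- rnorm(5e4)
  ww <- whiten_ar1(w)
  expect_lt(abs(attr(ww, "phi")), 0.02)
  # AR(1) with phi = 0.9
  ar <- as.numeric(arima.sim(list(ar = 0.9), n = 1e5))
  wa <- whiten_ar1(ar)
  expect_equal(attr(wa, "phi"), 0.9, tolerance = 0.025)
  expect_lt(abs(acf(wa, plot = FALSE)$acf[2]), 0.02)
  expect_error(whiten_ar1(rep(3, 100)), "constant")
  expect_error(whiten_ar1(1), "2 samples")
})

test_that("Gabor spectrogram localizes tones and tracks a chirp", {
  fs <- 250
  t <- (0:(fs * 10 - 1)) / fs
  grid <- seq(2, 100, by = 1)
  sg <- gabor_spectrogram(sin(2 * pi * 15 * t), fs, freqs = grid)
  expect_equal(grid[which.max(rowMeans(sg$magnitude))], 15)
  # unit-amplitude tone -> magnitude ~ 1 (amplitude normalisation)
  expect_equal(max(rowMeans(sg$magnitude)), 1, tolerance = 0.02)
  # time marginal flat away from edges
  inner <- colSums(sg$magnitude)[(fs):(9 * fs)]
  expect_lt(diff(range(inner)) / mean(inner), 0.1)
  # two tones -> two local maxima at the right rows
  x2 <- sin(2 * pi * 10 * t) + sin(2 * pi * 60 * t)
  m2 <- rowMeans(gabor_spectrogram(x2, fs, freqs = grid)$magnitude)
  pk <- peak_prominences(m2, grid)
  top2 <- sort(pk$x[order(-pk$prominence)][1:2])
  expect_equal(top2, c(10, 60), tolerance = 0.01)
  # chirp: ridge frequency increases monotonically
  ch <- sin(2 * pi * (5 * t + ((40 - 5) / (2 * 10)) * t^2))
  sgc <- gabor_spectrogram(ch, fs, freqs = seq(2, 60, by = 1),
                           time_downsample = 25)
  ridge <- sgc$freqs[apply(sgc$magnitude, 2, which.max)]
  inner_r <- ridge[10:(length(ridge) - 10)]
  expect_true(all(diff(inner_r) >= 0))
  expect_error(gabor_spectrogram(t, fs, freqs = numeric(0)), "empty")
  expect_error(gabor_spectrogram(t, fs, freqs = c(10, 200)), "Nyquist")
})

test_that("oscillatory epochs recover bursts and stay rare on noise", {
  fs <- 250
  set.seed(32)
  t <- (0:(fs * 30 - 1)) / fs
  x <- rnorm(length(t)) * 0.5 +
    50 * sin(2 * pi * 12 * t) * (t >= 10 & t < 11) +
    50 * sin(2 * pi * 12 * t) * (t >= 20 & t < 22)
  ep <- detect_oscillatory_epochs(x, fs)
  expect_equal(nrow(ep$intervals), 2)
  expect_lt(abs(ep$intervals$start_s[1] - 10), 0.1)
  expect_lt(abs(ep$intervals$end_s[1] - 11), 0.1)
  # arithmetic: totals over 1 s + 2 s bursts
  expect_equal(ep$total_duration_s, 3, tolerance = 0.2)
  expect_equal(ep$mean_duration_s, 1.5, tolerance = 0.1)
  # pure Gaussian noise: <= 2% of the record
  xg <- rnorm(fs * 60)
  expect_lte(detect_oscillatory_epochs(xg, fs)$total_duration_s / 60, 0.02)
  # amplitude equivariance of the threshold
  ep2 <- detect_oscillatory_epochs(3 * x, fs)
  expect_equal(ep2$threshold / ep$threshold, 3, tolerance = 1e-9)
  expect_identical(ep2$intervals, ep$intervals)
  expect_error(detect_oscillatory_epochs(rnorm(fs), fs), "10 s")
})

test_that("twitch-triggered spectrogram shows post-twitch spindle power", {
  fs <- 250
  tw <- seq(10, 190, by = 3.7)
  ev <- data.frame(start_s = tw + 0.1, duration_s = 0.6, freq_hz = 14)
  spec <- synth_lfp_spec(n_channels = 1, fs = fs, duration = 200,
                         events = ev, event_amplitude = 100)
  g <- generate_lfp(spec, 31)
  sg <- gabor_spectrogram(g$recording$signal[1, ], fs,
                          freqs = exp(seq(log(2), log(80), length.out = 30)))
  tts <- twitch_triggered_spectrogram(sg, tw, window = 1.5)
  sp_rows <- tts$freqs >= 10 & tts$freqs <= 20
  post <- tts$lags > 0.15 & tts$lags < 0.55
  expect_gt(mean(tts$z[sp_rows, post]), 1)
  # coincidence zeroing
  expect_true(all(tts$z[, abs(tts$lags) <= 0.05] == 0))
  # shuffled twitch times: no consistent structure
  set.seed(33)
  tts0 <- twitch_triggered_spectrogram(sg, runif(50, 2, 198), window = 1.5)
  expect_lt(mean(abs(tts0$z[sp_rows, post])), 0.5)
  expect_error(twitch_triggered_spectrogram(sg, numeric(0)), "twitch")
})

test_that("twitch-event cross-correlogram flags the built-in lag only", {
  set.seed(34)
  tw <- sort(runif(60, 5, 295))
  xc <- twitch_event_xcorr(tw, tw + 0.25, span = 300, n_shuffle = 200)
  sig_pos <- xc$lags[xc$exceeds & xc$counts > xc$ci_high]
  expect_true(any(abs(sig_pos - 0.25) < 0.051))
  # independent Poisson series: few flags
  xc0 <- twitch_event_xcorr(sort(runif(60, 0, 300)), sort(runif(60, 0, 300)),
                            span = 300, n_shuffle = 200)
  expect_lte(mean(xc0$exceeds), 0.10)
  expect_error(twitch_event_xcorr(tw, numeric(0), span = 300), "empty")
  expect_error(twitch_event_xcorr(tw, tw, span = 300, n_shuffle = 0),
               "n_shuffle")
})

test_that("aperiodic exponent is recovered with peaks masked", {
  f <- seq(1, 100, by = 0.5)
  expect_equal(aperiodic_exponent(f, f^-2)$exponent, 2, tolerance = 0.05)
  expect_equal(aperiodic_exponent(f, rep(2, length(f)))$exponent, 0,
               tolerance = 0.05)
  withpk <- f^-1.5 + dnorm(f, 12, 1) * 0.05
  fit <- aperiodic_exponent(f, withpk)
  expect_equal(fit$exponent, 1.5, tolerance = 0.1)
  expect_gt(fit$n_masked, 0)
  bad <- rep(1, length(f)); bad[f == 10] <- -1
  expect_error(aperiodic_exponent(f, bad), "non-positive")
  expect_error(aperiodic_exponent(f[1:5], f[1:5]^-1, band = c(1, 2)),
               "10 frequencies")
})

test_that("wavelet power agrees with variance for stationary noise", {
  set.seed(35)
  fs <- 250
  x <- bandpass_filter(rnorm(fs * 120, sd = 10), fs, 4, 60)
  # Parseval-style check of the transform normalisation. For the analytic
  # Gabor wavelet with transfer 2*exp(-2*pi^2*sigma_t^2*(f-f0)^2) and a
  # smooth one-sided PSD S1, E|W|^2(f0) = 4*sqrt(pi)*f0*S1(f0)/cycles, so
  # S1 can be recovered from the row means and integrated over the band to
  # reproduce the signal variance.
  cycles <- 5
  grid <- exp(seq(log(2), log(80), length.out = 60))
  sg <- gabor_spectrogram(x, fs, freqs = grid, cycles = cycles)
  s1_hat <- cycles * rowMeans(sg$magnitude^2) / (2 * sqrt(pi) * grid)
  mids <- (grid[-1] + grid[-length(grid)]) / 2
  est_var <- sum(diff(grid) * (s1_hat[-1] + s1_hat[-length(grid)]) / 2)
  expect_equal(est_var / var(x), 1, tolerance = 0.15)
})
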