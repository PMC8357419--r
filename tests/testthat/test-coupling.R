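test_that("comodulogram has unit diagonal, symmetry, and sane null", {
  set.seed(51)
  fs <- 250
  g <- fixture_lfp(seed = 151, duration = 90, n_events = 15, fs = fs)
  gt <- g$events[g$events$channel == 1, ]
  cmg <- comodulogram(g$recording$signal[1, ], fs,
                      (gt$start_s + gt$end_s) / 2)
  expect_equal(diag(cmg$corr), rep(1, length(cmg$freqs)))
  expect_equal(cmg$corr, t(cmg$corr), tolerance = 1e-12)
  expect_true(all(abs(cmg$corr) <= 1 + 1e-12))
  # 60 Hz rows dropped from the default grid
  expect_false(any(abs(cmg$freqs - 60) <= 2))
  expect_error(comodulogram(g$recording$signal[1, ], fs, c(1, 2)), "5 events")
})

test_that("shared-envelope carriers correlate and are flagged significant", {
  set.seed(52)
  fs <- 250
  t <- (0:(fs * 200 - 1)) / fs
  env <- abs(gaussian_smooth(rnorm(length(t)), fs * 0.3)) + 0.05
  x <- env * sin(2 * pi * 15 * t) + env * sin(2 * pi * 50 * t) +
    0.1 * rnorm(length(t))
  cmg <- comodulogram(x, fs, seq(5, 195, by = 10), window = 4)
  i15 <- which.min(abs(cmg$freqs - 15))
  i50 <- which.min(abs(cmg$freqs - 50))
  expect_gt(cmg$corr[i15, i50], 0.5)
  expect_true(cmg$significant[i15, i50])
})

test_that("coupling curve sums spindle columns and gates on significance", {
  set.seed(53)
  g <- fixture_lfp(seed = 153, duration = 90, n_events = 15, fs = 250)
  gt <- g$events[g$events$channel == 1, ]
  cmg <- comodulogram(g$recording$signal[1, ], 250,
                      (gt$start_s + gt$end_s) / 2)
  curve <- spindle_coupling_curve(cmg)
  cols <- cmg$freqs >= 10 & cmg$freqs <= 20
  masked <- cmg$corr
  masked[!cmg$significant & row(masked) != col(masked)] <- 0
  expect_equal(curve$curve, rowSums(masked[, cols, drop = FALSE]))
  expect_true(all(curve$excluded[cmg$freqs >= 8 & cmg$freqs <= 25]))
  expect_error(spindle_coupling_curve(
    comodulogram(g$recording$signal[1, ], 250,
                 (gt$start_s + gt$end_s) / 2, freqs = c(30, 40, 50, 70, 90)),
    spindle_band = c(10, 20)), "10-20")
})

test_that("peak prominence and width match the brute-force definitions", {
  # analytically placed Gaussian bump on a flat baseline
  x <- seq(0, 100, by = 0.5)
  y <- 2 * exp(-(x - 40)^2 / (2 * 3^2))
  pk <- peak_prominences(y, x)
  main <- pk[which.max(pk$prominence), ]
  expect_equal(main$x, 40)
  expect_equal(main$prominence, 2, tolerance = 1e-6)
  # half-prominence width of a Gaussian: 2*sigma*sqrt(2*ln 2)
  expect_equal(main$width, 2 * 3 * sqrt(2 * log(2)), tolerance = 0.05)
  # coupling-index arithmetic: value 2, prominence 1, width 4 -> 0.5
  expect_equal(2.0 * 1.0 / 4, 0.5)
})

test_that("retained peaks respect prominence and width rules", {
  mk_curve <- function(y, f = seq_along(y)) {
    structure(list(freqs = f, curve = y,
                   excluded = rep(FALSE, length(y)),
                   spindle_band = c(10, 20)),
              class = "coupling_curve")
  }
  f <- seq(30, 90, by = 1)
  y <- 2 * exp(-(f - 50)^2 / (2 * 2^2))
  pk <- detect_coupling_peaks(mk_curve(y, f))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$f_c, 50, tolerance = 0.5)
  expect_equal(pk$coupling_index, pk$value * pk$prominence / pk$width)
  # prominence 0.5 rejected
  pk2 <- detect_coupling_peaks(mk_curve(0.25 * y, f))
  expect_equal(nrow(pk2), 0)
  # literal width rule Delta_f < 1/f_c rejects this broad peak
  pk3 <- detect_coupling_peaks(mk_curve(y, f), width_rule = "literal")
  expect_equal(nrow(pk3), 0)
})

test_that("AUC is a trapezoidal band integral", {
  mk_curve <- function(y, f) {
    structure(list(freqs = f, curve = y,
                   excluded = rep(FALSE, length(y)),
                   spindle_band = c(10, 20)),
              class = "coupling_curve")
  }
  f <- seq(20, 40, by = 0.5)
  expect_equal(coupling_auc(mk_curve(rep(3, length(f)), f), c(25, 35)),
               3 * 10, tolerance = 1e-9)
  expect_equal(coupling_auc(mk_curve(rep(0, length(f)), f), c(25, 35)), 0)
  # bump of known integral: Gaussian inside the band
  y <- exp(-(f - 30)^2 / (2 * 1.5^2))
  expect_equal(coupling_auc(mk_curve(y, f), c(25, 35)),
               1.5 * sqrt(2 * pi), tolerance = 0.01 * 1.5 * sqrt(2 * pi))
  expect_error(coupling_auc(mk_curve(f, f), c(10, 35)), "support")
})

test_that("gamma-coupled events yield a retained peak near the carrier", {
  hits <- 0
  grid <- comodulogram_grid()
  near <- which.min(abs(grid - 50))
  tol <- max(diff(grid)[c(near - 1, near)])
  for (s in 1:4) {
    spec <- synth_lfp_spec(n_channels = 1, fs = 250, duration = 120,
                           n_events = 20, gamma_coupling = TRUE,
                           gamma_freq = 50, gamma_coef = 0.8)
    g <- generate_lfp(spec, s)
    gt <- g$events[g$events$channel == 1, ]
    pk <- detect_coupling_peaks(spindle_coupling_curve(
      comodulogram(g$recording$signal[1, ], 250,
                   (gt$start_s + gt$end_s) / 2)))
    hits <- hits + (nrow(pk) > 0 && any(abs(pk$f_c - 50) <= tol))
  }
  expect_gte(hits, 3)
})
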