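#' Default comodulogram frequency grid
#'
#' Log-spaced 1-100 Hz, 40 points, with rows within 2 Hz of 60 Hz dropped to
#' avoid line-noise-driven spurious correlations.
#'
#' @param n number of grid points before the 60 Hz exclusion.
#' @param range frequency range (Hz).
#' @param notch frequency whose neighborhood is excluded (set `NA` to keep).
#' @return numeric vector of frequencies.
#' @export
comodulogram_grid <- function(n = 40L, range = c(1, 100), notch = 60) {
  f <- exp(seq(log(range[1L]), log(range[2L]), length.out = n))
  if (!is.na(notch)) f <- f[abs(f - notch) > 2]
  f
}

#' Event-locked amplitude-amplitude comodulogram
#'
#' For each grid frequency, the Gabor wavelet magnitude of the raw signal is
#' smoothed with a Gaussian whose duration is matched to the frequency
#' (sigma = 2 cycles). Samples within a window around each spindle-band
#' event are pooled and the frequency-by-frequency correlation matrix of
#' log magnitudes is computed, with a significance mask at p < 0.05 after
#' Bonferroni-Holm correction across the upper triangle.
#'
#' @param x raw signal (uV).
#' @param fs sampling rate (Hz).
#' @param event_times event center times (s); at least 5.
#' @param window full window length around each event (s).
#' @param freqs frequency grid; defaults to [comodulogram_grid()].
#' @param cycles wavelet cycles; the default (10) is higher than for
#'   spectrograms, trading temporal for frequency resolution so that
#'   between-band correlations localize sharply in frequency.
#' @param method `"pearson"` (on log magnitudes) or `"spearman"`.
#' @return object of class `comodulogram`: `corr` (symmetric, unit
#'   diagonal), `pval`, `significant` (Holm-corrected mask), `freqs`,
#'   `n_events`, `window`.
#' @export
comodulogram <- function(x, fs, event_times, window = 4, freqs = NULL,
                         cycles = 10, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(event_times) < 5L) stop("need at least 5 events")
  if (is.null(freqs)) freqs <- comodulogram_grid()
  freqs <- freqs[freqs < fs / 2]
  n <- length(x)
  half <- round(window / 2 * fs)
  centers <- round(event_times * fs) + 1L
  centers <- centers[centers - half >= 1L & centers + half <= n]
  if (length(centers) < 5L) stop("fewer than 5 events with a full window")
  idx <- unlist(lapply(centers, function(c0) (c0 - half):(c0 + half)),
                use.names = FALSE)
  m <- matrix(0, length(idx), length(freqs))
  for (i in seq_along(freqs)) {
    mag <- Mod(gabor_coefficients(x, fs, freqs[i], cycles))
    mag <- gaussian_smooth(mag, 2 / freqs[i] * fs)   # sigma = 2 cycles
    m[, i] <- log10(mag[idx] + 1e-12)
  }
  if (method == "spearman") m <- apply(m, 2L, rank)
  corr <- stats::cor(m)
  nf <- length(freqs)
  # Effective sample sizes: the magnitude series are strongly
  # autocorrelated (wavelet temporal width + frequency-matched smoothing),
  # so the nominal sample count wildly overstates the degrees of freedom.
  # For Gaussian-equivalent temporal scales s_i, s_j the integral of the
  # product of the two autocorrelation functions is
  # 2*sqrt(pi)*s_i*s_j/sqrt(s_i^2+s_j^2), and n_eff = T / that integral.
  sig_t <- sqrt((2 / freqs)^2 + (cycles / (2 * pi * freqs))^2)
  total_t <- nrow(m) / fs
  r <- corr
  r[abs(r) >= 1] <- sign(r[abs(r) >= 1]) * (1 - 1e-15)
  pval <- matrix(0, nf, nf)
  for (i in seq_len(nf)) {
    for (j in seq_len(nf)) {
      if (i == j) next
      tau <- 2 * sqrt(pi) * sig_t[i] * sig_t[j] /
        sqrt(sig_t[i]^2 + sig_t[j]^2)
      n_eff <- max(total_t / tau, 5)
      tstat <- r[i, j] * sqrt((n_eff - 2) / (1 - r[i, j]^2))
      pval[i, j] <- 2 * stats::pt(-abs(tstat), df = n_eff - 2)
    }
  }
  ut <- upper.tri(pval)
  p_adj <- matrix(1, nf, nf)
  p_adj[ut] <- stats::p.adjust(pval[ut], method = "holm")
  p_adj <- pmin(p_adj, t(p_adj))
  diag(p_adj) <- 0
  structure(list(corr = corr, pval = pval,
                 significant = p_adj < 0.05 & row(corr) != col(corr),
                 freqs = freqs, n_events = length(centers), window = window),
            class = "comodulogram")
}

#' Spindle-band coupling curve
#'
#' Sums the comodulogram columns belonging to the spindle band (10-20 Hz)
#' to obtain, for every frequency, the magnitude of its comodulation with
#' the spindle band. By default only Holm-significant matrix entries
#' contribute (non-significant correlations are treated as zero), so the
#' curve reflects reliable comodulation rather than sampling noise. Rows
#' inside the spindle detection band are marked for exclusion from the
#' subsequent peak search (self-coupling block).
#'
#' @param cmg a [comodulogram()].
#' @param spindle_band columns summed (Hz).
#' @param exclude_band rows excluded from peak search (Hz); defaults to the
#'   full 8-25 Hz detection band to keep wavelet-bandwidth shoulders of the
#'   self-block out of the peak list.
#' @param mask_nonsignificant zero non-significant correlations before
#'   summation.
#' @return object of class `coupling_curve`: `freqs`, `curve`, `excluded`
#'   (logical per row), `spindle_band`.
#' @export
spindle_coupling_curve <- function(cmg, spindle_band = c(10, 20),
                                   exclude_band = c(8, 25),
                                   mask_nonsignificant = TRUE) {
  stopifnot(inherits(cmg, "comodulogram"))
  cols <- which(cmg$freqs >= spindle_band[1L] & cmg$freqs <= spindle_band[2L])
  if (!length(cols)) stop("frequency grid lacks 10-20 Hz support")
  cm <- cmg$corr
  if (mask_nonsignificant) cm[!cmg$significant & row(cm) != col(cm)] <- 0
  curve <- rowSums(cm[, cols, drop = FALSE])
  excluded <- cmg$freqs >= exclude_band[1L] & cmg$freqs <= exclude_band[2L]
  structure(list(freqs = cmg$freqs, curve = curve, excluded = excluded,
                 spindle_band = spindle_band),
            class = "coupling_curve")
}

#' Local maxima with prominence and half-prominence width
#'
#' Topographic peak analysis of a 1-D curve: prominence of a peak is its
#' height above the higher of the two minima separating it from the nearest
#' higher terrain (or the curve ends); width is measured between the
#' half-prominence crossings on each side, linearly interpolated in `x`.
#'
#' @param y curve values.
#' @param x abscissa (same length); defaults to indices.
#' @return data.frame with `index`, `x`, `value`, `prominence`, `width`.
#' @export
peak_prominences <- function(y, x = seq_along(y)) {
  n <- length(y)
  peaks <- which(diff(sign(diff(y))) < 0) + 1L
  out <- data.frame(index = integer(0), x = numeric(0), value = numeric(0),
                    prominence = numeric(0), width = numeric(0))
  for (p in peaks) {
    i <- p
    left_min <- y[p]
    while (i > 1L && y[i - 1L] <= y[p]) {
      i <- i - 1L
      left_min <- min(left_min, y[i])
    }
    if (i == 1L && y[1L] <= y[p]) left_min <- min(left_min, y[1L])
    j <- p
    right_min <- y[p]
    while (j < n && y[j + 1L] <= y[p]) {
      j <- j + 1L
      right_min <- min(right_min, y[j])
    }
    prom <- y[p] - max(left_min, right_min)
    h <- y[p] - prom / 2
    li <- p
    while (li > 1L && y[li - 1L] > h) li <- li - 1L
    xl <- if (li == 1L || y[li] == h) x[li] else {
      x[li - 1L] + (x[li] - x[li - 1L]) * (h - y[li - 1L]) / (y[li] - y[li - 1L])
    }
    ri <- p
    while (ri < n && y[ri + 1L] > h) ri <- ri + 1L
    xr <- if (ri == n || y[ri] == h) x[ri] else {
      x[ri] + (x[ri + 1L] - x[ri]) * (h - y[ri]) / (y[ri + 1L] - y[ri])
    }
    out <- rbind(out, data.frame(index = p, x = x[p], value = y[p],
                                 prominence = prom, width = xr - xl))
  }
  out
}

#' Detect retained coupling peaks
#'
#' Local maxima of the coupling curve outside the spindle self-block, kept
#' when prominence exceeds `prominence_min` and the width rule holds. The
#' width rule `"relative"` requires the half-prominence width to be smaller
#' than the center frequency (quality factor > 1); `"literal"` applies the
#' printed form `width < 1/f_c`. Each retained peak carries the coupling
#' index `(value x prominence) / width`.
#'
#' Retained peak centers are refined off-grid by parabolic interpolation
#' through the peak sample and its two neighbours in log-frequency.
#'
#' @param curve_obj a [spindle_coupling_curve()] result.
#' @param prominence_min minimum prominence.
#' @param width_rule `"relative"` or `"literal"`.
#' @return data.frame with `f_c` (refined), `grid_freq` (grid sample),
#'   `value`, `prominence`, `width`, `coupling_index` (possibly zero rows).
#' @export
detect_coupling_peaks <- function(curve_obj, prominence_min = 0.75,
                                  width_rule = c("relative", "literal")) {
  stopifnot(inherits(curve_obj, "coupling_curve"))
  width_rule <- match.arg(width_rule)
  if (length(curve_obj$curve) < 5L) stop("curve too short")
  pk <- peak_prominences(curve_obj$curve, curve_obj$freqs)
  if (nrow(pk)) pk <- pk[!curve_obj$excluded[pk$index], , drop = FALSE]
  if (nrow(pk)) {
    ok <- pk$prominence > prominence_min &
      if (width_rule == "relative") pk$width < pk$x else pk$width < 1 / pk$x
    pk <- pk[ok, , drop = FALSE]
  }
  # sub-grid refinement: parabolic interpolation of the vertex through the
  # peak sample and its two neighbours, in log-frequency
  f_c <- pk$x
  y <- curve_obj$curve
  lf <- log(curve_obj$freqs)
  for (k in seq_len(nrow(pk))) {
    i <- pk$index[k]
    if (i <= 1L || i >= length(y)) next
    denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
    if (denom >= 0) next
    delta <- 0.5 * (y[i - 1L] - y[i + 1L]) / denom
    delta <- max(min(delta, 0.5), -0.5)
    step <- if (delta >= 0) lf[i + 1L] - lf[i] else lf[i] - lf[i - 1L]
    f_c[k] <- exp(lf[i] + delta * step)
  }
  data.frame(f_c = f_c, grid_freq = pk$x, value = pk$value,
             prominence = pk$prominence, width = pk$width,
             coupling_index = if (nrow(pk)) pk$value * pk$prominence / pk$width
                              else numeric(0))
}

#' Area under the coupling curve over a band
#'
#' Trapezoidal integral of the coupling curve between two frequencies
#' (e.g., 25-35 Hz for the infant gamma-coupling quantification).
#'
#' @param curve_obj a [spindle_coupling_curve()].
#' @param band integration band (Hz); must lie within the curve support.
#' @return scalar AUC.
#' @export
coupling_auc <- function(curve_obj, band = c(25, 35)) {
  stopifnot(inherits(curve_obj, "coupling_curve"))
  f <- curve_obj$freqs
  if (band[1L] < min(f) || band[2L] > max(f))
    stop("band outside curve support (", signif(min(f), 3), "-",
         signif(max(f), 3), " Hz)")
  # interpolate the curve onto the band edges, then trapezoid
  grid <- sort(unique(c(band, f[f > band[1L] & f < band[2L]])))
  yv <- stats::approx(f, curve_obj$curve, xout = grid)$y
  sum(diff(grid) * (utils::head(yv, -1L) + utils::tail(yv, -1L)) / 2)
}
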