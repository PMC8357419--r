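#' Fit developmental trajectories with LOOCV model selection
#'
#' Fits polynomial regressions of feature value on age for degrees 1 to
#' `d_max` and selects the degree by leave-one-out cross-validation (one
#' animal = one left-out unit; the LOO residuals are computed exactly via
#' the hat matrix). With `selection = "one_se"` (default) the smallest
#' degree whose LOOCV MSE lies within one standard error of the minimum is
#' chosen — the standard parsimony rule, which keeps selection noise from
#' promoting spurious high-degree fits; `selection = "min"` takes the bare
#' minimum. The per-age mean residual of the linear fit is reported as a
#' diagnostic of systematic lack of fit.
#'
#' @param data data.frame with `age` and `value` (one row per animal).
#' @param d_max maximum polynomial degree searched.
#' @param selection `"one_se"` or `"min"`.
#' @return object of class `trajectory_fit`: `best` (list with `degree`,
#'   `coefficients` raw-polynomial lowest-first, `loocv_mse`), `candidates`
#'   (data.frame `degree`, `loocv_mse`), `linear_residual_by_age`
#'   (data.frame `age`, `mean_residual`), `data`.
#' @export
fit_trajectory <- function(data, d_max = 5L,
                           selection = c("one_se", "min")) {
  selection <- match.arg(selection)
  stopifnot(all(c("age", "value") %in% names(data)))
  n <- nrow(data)
  if (length(unique(data$age)) < 3L) stop("need at least 3 distinct ages")
  if (n <= d_max + 1L)
    stop("need more animals (", n, ") than d_max + 1 (", d_max + 1L, ")")
  cand <- data.frame(degree = seq_len(d_max), loocv_mse = NA_real_,
                     loocv_se = NA_real_)
  fits <- vector("list", d_max)
  for (d in seq_len(d_max)) {
    X <- stats::poly(data$age, degree = d, raw = TRUE)
    fit <- stats::lm(data$value ~ X)
    h <- stats::hatvalues(fit)
    loo <- stats::residuals(fit) / (1 - h)
    cand$loocv_mse[d] <- mean(loo^2)
    cand$loocv_se[d] <- stats::sd(loo^2) / sqrt(n)
    fits[[d]] <- fit
  }
  i_min <- which.min(cand$loocv_mse)
  best_d <- if (selection == "min") cand$degree[i_min] else {
    cutoff <- cand$loocv_mse[i_min] + cand$loocv_se[i_min]
    cand$degree[which(cand$loocv_mse <= cutoff)[1L]]
  }
  res1 <- stats::residuals(fits[[1L]])
  lin_diag <- stats::aggregate(res1, by = list(age = data$age), FUN = mean)
  names(lin_diag)[2L] <- "mean_residual"
  structure(list(
    best = list(degree = best_d,
                coefficients = unname(stats::coef(fits[[best_d]])),
                loocv_mse = cand$loocv_mse[best_d]),
    candidates = cand,
    linear_residual_by_age = lin_diag,
    data = data
  ), class = "trajectory_fit")
}

# fit a raw polynomial of given degree, return coefficients lowest-first;
# ages are centered/scaled internally for conditioning
polyfit_raw <- function(age, value, degree) {
  mu <- mean(age); sc <- stats::sd(age)
  z <- (age - mu) / sc
  X <- cbind(1, stats::poly(z, degree = degree, raw = TRUE))
  cf_z <- tryCatch(qr.coef(qr(X), value), error = function(e) rep(NA_real_, degree + 1L))
  if (anyNA(cf_z)) return(NULL)
  # convert coefficients in z back to raw age: value = sum cf_z[k] ((a-mu)/sc)^k
  cf <- numeric(degree + 1L)
  for (k in 0:degree) {
    # expand cf_z[k+1] * (a - mu)^k / sc^k
    bin <- choose(k, 0:k) * (-mu)^(k - (0:k))
    cf[1:(k + 1L)] <- cf[1:(k + 1L)] + cf_z[k + 1L] / sc^k * bin
  }
  cf
}

#' Bootstrap localization of a trajectory's first interior extremum
#'
#' Resamples animals with replacement within each age, jitters ages
#' uniformly over +-`jitter/2`, refits the selected polynomial degree, and
#' records the age of the first interior extremum (smallest age where the
#' fitted derivative changes sign inside the observed range). Repeating
#' `n_boot` times yields the within-age probability distribution of the
#' extremum location. A null distribution is built identically except that
#' feature values are resampled across all ages (decoupling value from
#' age). Probability mass is reported over 1-age-unit bins plus an explicit
#' "no interior extremum" mass.
#'
#' @param data data.frame with `age`, `value`.
#' @param degree polynomial degree of the selected model (>= 2).
#' @param n_boot number of resamples per distribution.
#' @param jitter total jitter window (age units).
#' @param seed integer random seed.
#' @return object of class `nadir_result`: `bins` (bin lower edges),
#'   `within_mass`, `null_mass` (each summing to 1 with `within_none` /
#'   `null_none`), `mode_age` (midpoint of the maximal within-mass bin),
#'   `exceedance` (within mass / null mass at the mode bin).
#' @export
bootstrap_nadir <- function(data, degree, n_boot = 10000L, jitter = 0.5,
                            seed = 1L) {
  if (degree < 2L)
    stop("degree-1 model admits no interior extremum; skip the bootstrap")
  set.seed(seed)
  ages <- data$age
  vals <- data$value
  rng <- range(ages)
  by_age <- split(seq_along(ages), ages)
  n <- length(ages)
  one_extremum <- function(a, v) {
    cf <- polyfit_raw(a, v, degree)
    if (is.null(cf)) return(NA_real_)
    first_interior_extremum(cf, rng)
  }
  draw_within <- function() {
    idx <- unlist(lapply(by_age, function(ii)
      ii[sample.int(length(ii), length(ii), replace = TRUE)]),
      use.names = FALSE)
    idx
  }
  within <- numeric(n_boot)
  nulls <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- draw_within()
    a <- ages[idx] + stats::runif(n, -jitter / 2, jitter / 2)
    within[b] <- one_extremum(a, vals[idx])
    # null: values drawn with replacement across all ages
    vnull <- vals[sample.int(n, n, replace = TRUE)]
    a2 <- ages + stats::runif(n, -jitter / 2, jitter / 2)
    nulls[b] <- one_extremum(a2, vnull)
  }
  bins <- seq(floor(rng[1L]), ceiling(rng[2L]) - 1L)
  mass <- function(x) {
    h <- vapply(bins, function(b0) sum(!is.na(x) & x >= b0 & x < b0 + 1), 0)
    list(mass = h / length(x), none = sum(is.na(x)) / length(x))
  }
  mw <- mass(within); mn <- mass(nulls)
  mode_bin <- which.max(mw$mass)
  structure(list(
    bins = bins, within_mass = mw$mass, null_mass = mn$mass,
    within_none = mw$none, null_none = mn$none,
    mode_age = bins[mode_bin] + 0.5,
    exceedance = mw$mass[mode_bin] / max(mn$mass[mode_bin], 1 / n_boot)
  ), class = "nadir_result")
}

#' Combinatorial maturation metric from spindle features
#'
#' Combines per-animal waveform asymmetry (A), spatial extent (S) and power
#' (P) into one maturation score. The default rule is the mean of the
#' within-cohort z-scores of S, -A and -P, so the metric rises as events
#' become more spatially extensive, more symmetric and lower power (the
#' mature direction for each feature) and is invariant to per-feature
#' affine rescaling. Alternative rules: `"product"` (product of shifted
#' z-scores is not affine-invariant and is provided for exploration only)
#' and `"pc1"` (first principal component, sign-aligned with S).
#'
#' @param features data.frame with `animal_id`, `A`, `S`, `P`.
#' @param rule `"zmean"`, `"product"` or `"pc1"`.
#' @return data.frame `animal_id`, `metric`; the rule id is attached as
#'   attribute `rule`.
#' @export
combinatorial_metric <- function(features, rule = c("zmean", "product",
                                                    "pc1")) {
  rule <- match.arg(rule)
  for (col in c("A", "S", "P")) {
    if (!col %in% names(features) || anyNA(features[[col]]))
      stop("missing feature `", col, "`")
  }
  z <- function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  zs <- cbind(S = z(features$S), A = -z(features$A), P = -z(features$P))
  metric <- switch(rule,
    zmean = rowMeans(zs),
    product = apply(zs + 3, 1L, prod),
    pc1 = {
      pc <- stats::prcomp(zs, center = TRUE, scale. = FALSE)
      sc <- pc$x[, 1L]
      if (stats::cor(sc, features$S) < 0) sc <- -sc
      sc
    })
  out <- data.frame(animal_id = features$animal_id, metric = metric)
  attr(out, "rule") <- rule
  out
}

#' Coarse decision-tree classifier of oscillation maturity
#'
#' Trains a depth-limited decision tree (at most 4 splits) on spatial
#' extent and waveform asymmetry to classify events as originating from
#' immature or mature animals, reporting stratified cross-validated
#' accuracy and the per-class marginal distributions of both features.
#'
#' @param events data.frame with `extent`, `esr` and `label` (factor or
#'   character with two classes, e.g. `"immature"` / `"mature"`).
#' @param folds number of stratified CV folds.
#' @param min_per_class minimum events per class.
#' @param seed integer seed for fold assignment.
#' @return object of class `maturity_tree`: `model` (rpart), `cv_accuracy`,
#'   `confusion` (CV-pooled), `marginals` (list of per-class histograms of
#'   `extent` and `esr`).
#' @export
maturity_tree <- function(events, folds = 5L, min_per_class = 20L,
                          seed = 1L) {
  stopifnot(all(c("extent", "esr", "label") %in% names(events)))
  events$label <- factor(events$label)
  if (nlevels(events$label) < 2L) stop("need two classes")
  tab <- table(events$label)
  if (any(tab < min_per_class))
    stop("each class needs at least ", min_per_class, " events")
  set.seed(seed)
  ctrl <- rpart::rpart.control(maxdepth = 4L, cp = 0.01, minsplit = 10L)
  # stratified fold assignment
  fold <- integer(nrow(events))
  for (lv in levels(events$label)) {
    i <- which(events$label == lv)
    fold[i] <- sample(rep_len(seq_len(folds), length(i)))
  }
  pred <- factor(rep(NA_character_, nrow(events)),
                 levels = levels(events$label))
  for (f in seq_len(folds)) {
    tr <- events[fold != f, , drop = FALSE]
    te <- events[fold == f, , drop = FALSE]
    m <- rpart::rpart(label ~ extent + esr, data = tr, method = "class",
                      control = ctrl)
    pred[fold == f] <- stats::predict(m, te, type = "class")
  }
  model <- rpart::rpart(label ~ extent + esr, data = events,
                        method = "class", control = ctrl)
  brk_extent <- seq(0, 1, by = 0.1)
  brk_esr <- c(seq(0, 3, by = 0.25), Inf)
  marg <- lapply(split(events, events$label), function(d) {
    list(extent = table(cut(d$extent, breaks = brk_extent,
                            include.lowest = TRUE)) / nrow(d),
         esr = table(cut(d$esr, breaks = brk_esr)) / nrow(d))
  })
  structure(list(model = model,
                 cv_accuracy = mean(pred == events$label),
                 confusion = table(truth = events$label, predicted = pred),
                 marginals = marg),
            class = "maturity_tree")
}
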