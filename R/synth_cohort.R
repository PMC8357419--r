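#' Specification for a synthetic developmental cohort
#'
#' Per-animal feature values follow a polynomial mean trajectory of age plus
#' Gaussian noise. The trajectory's true first interior extremum (the
#' "nadir" when it is a minimum) is derived analytically from the
#' coefficients and stored for downstream parameter-recovery testing.
#'
#' Defaults emulate a rodent cohort recorded daily over postnatal days 5-14
#' with 7 animals per day and a quadratic feature trajectory whose vertex
#' (true nadir) sits at age 8.5; the noise SD is 30% of the range of the
#' mean trajectory over the observed ages.
#'
#' @param ages distinct ages (days or weeks); at least 3.
#' @param n_per_age animals per age.
#' @param coefs polynomial coefficients of the mean trajectory, lowest
#'   degree first (`c(a0, a1, a2, ...)`).
#' @param noise_sd Gaussian noise SD; `NULL` = 0.3 x range of the mean
#'   trajectory over `ages`.
#' @param feature feature name carried through the output.
#' @return list of class `cohort_spec` with derived element `true_nadir`
#'   (NA when the trajectory has no interior extremum).
#' @export
cohort_spec <- function(ages = 5:14, n_per_age = 7L,
                        coefs = c(72.25, -17, 1), noise_sd = NULL,
                        feature = "feature") {
  ages <- sort(unique(ages))
  if (length(ages) < 3L) stop("need at least 3 distinct ages")
  mean_traj <- function(a) {
    vapply(a, function(ai) sum(coefs * ai^(seq_along(coefs) - 1L)), 0)
  }
  if (is.null(noise_sd)) {
    m <- mean_traj(ages)
    noise_sd <- 0.3 * (max(m) - min(m))
  }
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  true_nadir <- first_interior_extremum(coefs, range(ages))
  structure(list(ages = ages, n_per_age = as.integer(n_per_age),
                 coefs = coefs, noise_sd = noise_sd, feature = feature,
                 true_nadir = true_nadir),
            class = "cohort_spec")
}

# smallest real root of the derivative strictly inside `rng`, NA if none
first_interior_extremum <- function(coefs, rng) {
  d <- length(coefs) - 1L
  if (d < 2L) return(NA_real_)
  dcoef <- coefs[-1L] * seq_len(d)
  r <- polyroot(dcoef)
  r <- Re(r[abs(Im(r)) < 1e-8])
  r <- r[r > rng[1L] + 1e-9 & r < rng[2L] - 1e-9]
  if (!length(r)) return(NA_real_)
  min(r)
}

#' Generate a per-animal cohort feature table
#'
#' @param spec a [cohort_spec()].
#' @param seed integer random seed.
#' @return data.frame with `animal_id`, `age`, `feature`, `value`; the
#'   spec's `true_nadir` and `noise_sd` are attached as attributes.
#' @export
generate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  ages <- rep(spec$ages, each = spec$n_per_age)
  mean_val <- vapply(ages, function(a)
    sum(spec$coefs * a^(seq_along(spec$coefs) - 1L)), 0)
  out <- data.frame(
    animal_id = sprintf("a%03d", seq_along(ages)),
    age = ages,
    feature = spec$feature,
    value = mean_val + stats::rnorm(length(ages), sd = spec$noise_sd)
  )
  attr(out, "true_nadir") <- spec$true_nadir
  attr(out, "noise_sd") <- spec$noise_sd
  out
}
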