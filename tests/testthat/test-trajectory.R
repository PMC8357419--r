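test_that("LOOCV selects the generating model family", {
  # noiseless line: degree 1, near-zero LOOCV MSE
  d <- data.frame(age = rep(5:14, each = 3), value = rep(5:14, each = 3) * 2)
  d$value <- d$value + rnorm(nrow(d), sd = 1e-8)
  f <- fit_trajectory(d)
  expect_equal(f$best$degree, 1)
  expect_lt(f$best$loocv_mse, 1e-10)
  # selected model has the (one-SE-rule) minimal acceptable MSE
  expect_true(all(f$best$loocv_mse <=
                    f$candidates$loocv_mse + f$candidates$loocv_se))
  expect_error(fit_trajectory(data.frame(age = 5:8, value = 1:4),
                              d_max = 3), "more animals")
})

test_that("polynomial beats linear on cubic cohorts and not conversely", {
  lin_ok <- 0; cub_ok <- 0
  for (s in 1:10) {
    lin <- generate_cohort(cohort_spec(coefs = c(0, 3), noise_sd = 3),
                           seed = s)
    lin_ok <- lin_ok + (fit_trajectory(lin)$best$degree == 1)
    cub <- generate_cohort(cohort_spec(ages = 5:14, n_per_age = 6,
                                       coefs = c(-756, 255, -28, 1),
                                       noise_sd = 10), seed = s)
    cub_ok <- cub_ok + (fit_trajectory(cub)$best$degree >= 2)
  }
  expect_gte(lin_ok, 9)
  expect_gte(cub_ok, 9)
})

test_that("bootstrap localizes the quadratic vertex against the null", {
  co <- generate_cohort(cohort_spec(), seed = 7)   # vertex 8.5
  fit <- fit_trajectory(co)
  nad <- bootstrap_nadir(co, fit$best$degree, n_boot = 1000, seed = 11)
  expect_gte(nad$mode_age, 8)
  expect_lte(nad$mode_age, 9)
  expect_gte(nad$exceedance, 2)
  # distributions are proper probability masses
  expect_equal(sum(nad$within_mass) + nad$within_none, 1, tolerance = 1e-12)
  expect_equal(sum(nad$null_mass) + nad$null_none, 1, tolerance = 1e-12)
  # bit-for-bit reproducible given the seed
  nad2 <- bootstrap_nadir(co, fit$best$degree, n_boot = 1000, seed = 11)
  expect_identical(nad$within_mass, nad2$within_mass)
  expect_identical(nad$null_mass, nad2$null_mass)
  expect_error(bootstrap_nadir(co, 1), "skip")
})

test_that("monotone data forced through degree 2 yields mostly no extremum", {
  co <- generate_cohort(cohort_spec(coefs = c(0, 3), noise_sd = 1), seed = 5)
  nad <- bootstrap_nadir(co, 2, n_boot = 500, seed = 6)
  expect_gt(nad$within_none, max(nad$within_mass))
})

test_that("combinatorial metric is monotone and affine-invariant", {
  f <- data.frame(animal_id = sprintf("a%d", 1:10),
                  A = runif(10, 1, 2), S = runif(10), P = runif(10, 20, 80))
  m <- combinatorial_metric(f)
  expect_equal(attr(m, "rule"), "zmean")
  # identical animals: metric identically zero
  f0 <- data.frame(animal_id = c("a", "b", "c"), A = 1, S = 0.5, P = 30)
  expect_true(all(combinatorial_metric(f0)$metric == 0))
  # raising S for one animal raises its metric
  f2 <- f; f2$S[3] <- f2$S[3] + 0.5
  m2 <- combinatorial_metric(f2)
  expect_gt(m2$metric[3], m$metric[3])
  # affine rescaling of features leaves the default rule unchanged
  f3 <- f
  f3$A <- 10 * f3$A - 2; f3$S <- 0.1 * f3$S + 5; f3$P <- f3$P / 7
  expect_equal(combinatorial_metric(f3)$metric, m$metric, tolerance = 1e-12)
  expect_error(combinatorial_metric(f[, c("animal_id", "A", "S")]),
               "missing feature")
})

test_that("metric trajectory recovers the feature nadir by bootstrap", {
  # cohort where S rises and A, P fall past the transition: the combined
  # metric has an interior minimum near the programmed age
  set.seed(77)
  ages <- rep(5:14, each = 7)
  # S dips while A and P peak around the transition at 8.5, so the
  # combined metric (z(S) - z(A) - z(P)) has its interior minimum there
  S <- 0.3 + 0.02 * (ages - 8.5)^2 + rnorm(length(ages), sd = 0.08)
  A <- 2.0 - 0.04 * (ages - 8.5)^2 + rnorm(length(ages), sd = 0.15)
  P <- 100 - 2.5 * (ages - 8.5)^2 + rnorm(length(ages), sd = 10)
  f <- data.frame(animal_id = sprintf("a%d", seq_along(ages)),
                  A = A, S = S, P = P)
  m <- combinatorial_metric(f)
  d <- data.frame(age = ages, value = m$metric)
  nad <- bootstrap_nadir(d, 2, n_boot = 500, seed = 9)
  expect_gte(nad$mode_age, 7.5)
  expect_lte(nad$mode_age, 9.5)
})

test_that("maturity tree separates classes as their overlap dictates", {
  set.seed(78)
  # perfectly separated classes
  n <- 60
  ev <- data.frame(
    extent = c(runif(n, 0.05, 0.3), runif(n, 0.6, 0.95)),
    esr = c(runif(n, 1.6, 2.4), runif(n, 0.9, 1.2)),
    label = rep(c("immature", "mature"), each = n))
  mt <- maturity_tree(ev)
  expect_equal(mt$cv_accuracy, 1.0)
  # identical distributions: chance accuracy
  ev0 <- data.frame(extent = runif(2 * n), esr = runif(2 * n, 1, 2),
                    label = rep(c("immature", "mature"), each = n))
  expect_equal(maturity_tree(ev0)$cv_accuracy, 0.5, tolerance = 0.12)
  # realistic effect directions: immature small extent / high esr
  n2 <- 150
  ev2 <- data.frame(
    extent = c(pmin(pmax(rnorm(n2, 0.25, 0.12), 0.01), 1),
               pmin(pmax(rnorm(n2, 0.55, 0.18), 0.01), 1)),
    esr = c(rnorm(n2, 1.8, 0.35), rnorm(n2, 1.2, 0.25)),
    label = rep(c("immature", "mature"), each = n2))
  expect_gt(maturity_tree(ev2)$cv_accuracy, 0.85)
  expect_error(maturity_tree(ev2[ev2$label == "mature", ]), "two classes")
  expect_error(maturity_tree(ev2[c(1:5, 151:155), ]), "at least")
})
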