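test_that("fitting the exact implied matrix recovers the population model", {
  for (m in grid_models()) {
    mo <- as_moments(implied_sigma(m), 500)
    ml <- fit_cfa(mo, method = "ML", se = FALSE)
    expect_lt(ml$f_min, 1e-10)
    expect_true(ml$converged)
    expect_equal(ml$loadings, m$loadings, tolerance = 1e-5,
                 ignore_attr = TRUE)
    expect_equal(ml$unique_variances, m$unique_variances,
                 tolerance = 1e-5, ignore_attr = TRUE)
    uls <- fit_cfa(mo, method = "ULS")
    expect_lt(uls$f_min, 1e-10)
    expect_equal(uls$loadings, m$loadings, tolerance = 1e-5,
                 ignore_attr = TRUE)
  }
})

test_that("three-indicator fits reproduce the closed-form triad solution", {
  # saturated p = 3 model: lambda_1 = sqrt(r12 r13 / r23), etc.
  closed <- function(r12, r13, r23) {
    l1 <- sqrt(r12 * r13 / r23)
    c(l1, r12 / l1, r13 / l1)
  }

  # indefinite planted matrix: ULS needs no determinant and recovers the
  # Heywood solution theta1 = -2.6 exactly
  fu <- fit_cfa(as_moments(triad_planted(), 100), method = "ULS")
  expect_equal(fu$loadings, closed(.9, .8, .2), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(fu$unique_variances[1], -2.6, tolerance = 1e-6)
  expect_equal(fu$status, "heywood")
  expect_lt(fu$f_min, 1e-10)

  # ML requires a PD input; on PD triads it interpolates the same closed
  # form, including a PD Heywood case
  for (r in list(c(.9, .8, .6), c(.6, .5, .4), c(.7, .6, .5))) {
    mo <- as_moments(matrix(c(1, r[1], r[2],
                              r[1], 1, r[3],
                              r[2], r[3], 1), 3, 3), 200)
    fm <- fit_cfa(mo, method = "ML", se = FALSE)
    expect_equal(fm$loadings, closed(r[1], r[2], r[3]), tolerance = 1e-6,
                 ignore_attr = TRUE)
    fu <- fit_cfa(mo, method = "ULS")
    expect_equal(fu$loadings, closed(r[1], r[2], r[3]), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  fm <- fit_cfa(as_moments(triad_pd_heywood(), 200), method = "ML",
                se = FALSE)
  expect_equal(fm$unique_variances[1], -0.2, tolerance = 1e-6)
  expect_equal(fm$status, "heywood")

  # the indefinite matrix is rejected for ML with a diagnosable error
  expect_error(fit_cfa(as_moments(triad_planted(), 100), method = "ML"),
               "positive definite")
})

test_that("ML estimates match the profile-likelihood factor analysis of factanal", {
  mo <- seeded_moments(0.4, 6, 500, seed = 51)
  fit <- fit_cfa(mo, method = "ML", se = FALSE)
  expect_equal(fit$status, "proper")
  fa <- factanal(covmat = mo$R, factors = 1, n.obs = mo$n)
  sl <- standardized_loadings(fit, mo)
  expect_equal(sl, as.vector(fa$loadings), tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("ML and ULS agree on unit-variance inputs at large n", {
  mo <- seeded_moments(0.4, 5, 10000, seed = 61)
  ml <- fit_cfa(mo, method = "ML", se = FALSE)
  uls <- fit_cfa(mo, method = "ULS")
  expect_equal(standardized_loadings(ml, mo), uls$loadings,
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("ULS minimized value equals the recomputed residual sum of squares", {
  mo <- seeded_moments(0.3, 6, 300, seed = 71)
  fit <- fit_cfa(mo, method = "ULS")
  e <- tcrossprod(fit$loadings) - mo$R
  expect_equal(fit$f_min, sum(e[upper.tri(e)]^2), tolerance = 1e-10)
})

test_that("returned loading vectors have nonnegative sum (sign convention)", {
  for (s in 81:90) {
    mo <- seeded_moments(0.2, 4, 200, seed = s)
    expect_gte(sum(fit_cfa(mo, se = FALSE)$loadings), 0)
    expect_gte(sum(fit_cfa(mo, method = "ULS")$loadings), 0)
  }
})

test_that("solution classification separates proper, Heywood and nonconvergent", {
  f <- fit_cfa(seeded_moments(0.4, 6, 500, seed = 51), se = FALSE)
  expect_equal(classify_solution(f), "proper")
  f$unique_variances[1] <- -0.1
  expect_equal(classify_solution(f), "heywood")
  f$unique_variances[1] <- 0  # boundary counts as proper
  expect_equal(classify_solution(f), "proper")
  f$converged <- FALSE
  expect_equal(classify_solution(f), "nonconvergent")

  # weak loadings with few indicators produce both improper kinds
  st <- vapply(1:120, function(s)
    fit_cfa(seeded_moments(0.2, 4, 200, seed = 500 + s), se = FALSE)$status,
    "")
  expect_true(all(c("proper", "nonconvergent", "heywood") %in% st))
  ncv <- which(st == "nonconvergent")[1] + 500
  fnc <- fit_cfa(seeded_moments(0.2, 4, 200, seed = ncv), se = FALSE)
  expect_false(fnc$converged)
  expect_equal(fnc$n_iterations, 250)
})

test_that("standardized loadings are scale invariant and unit-variance consistent", {
  m <- one_factor_model(rep(0.4, 4))
  x <- generate_sample(m, 300, seed = 91)
  mo <- compute_moments(x)
  fit <- fit_cfa(mo, se = FALSE)
  sl <- standardized_loadings(fit, mo)
  # rescaling the indicators leaves the standardized solution unchanged
  xs <- unclass(x) %*% diag(c(2, 0.5, 10, 1))
  mos <- compute_moments(xs)
  fits <- fit_cfa(mos, se = FALSE)
  expect_equal(standardized_loadings(fits, mos), sl, tolerance = 1e-5)
  # standardized ML loadings equal a direct ML fit to R
  fitr <- fit_cfa(as_moments(mo$R, mo$n), se = FALSE)
  expect_equal(sl, fitr$loadings, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("standard errors are positive, shrink as 1/sqrt(N), and t follows", {
  ses <- function(N, seeds) {
    m <- t(vapply(seeds, function(s) {
      mo <- seeded_moments(0.4, 6, N, seed = s)
      fit_cfa(mo, method = "ML", se = TRUE)$standard_errors
    }, numeric(6)))
    colMeans(m[stats::complete.cases(m), , drop = FALSE])  # proper fits only
  }
  se200 <- ses(200, 101:130)
  se500 <- ses(500, 131:160)
  expect_true(all(se200 > 0) && all(se500 > 0))
  ratio <- mean(se500) / mean(se200)
  expect_equal(ratio, sqrt(200 / 500), tolerance = 0.2)

  fit <- fit_cfa(seeded_moments(0.4, 6, 500, seed = 51))
  tv <- loading_t_values(fit)
  expect_equal(tv, fit$loadings / fit$standard_errors)
  # strong-signal power: loadings significant essentially always
  tvals <- unlist(lapply(161:190, function(s)
    loading_t_values(fit_cfa(seeded_moments(0.4, 6, 500, seed = s)))))
  expect_gt(mean(abs(tvals) > 1.96), 0.99)
})
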