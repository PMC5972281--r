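test_that("sample generation is reproducible from its seed", {
  m <- one_factor_model(rep(0.3, 5))
  a <- generate_sample(m, 100, seed = 11)
  b <- generate_sample(m, 100, seed = 11)
  expect_identical(unclass(a), unclass(b))
  c <- generate_sample(m, 100, seed = 12)
  expect_false(identical(unclass(a), unclass(c)))
  expect_error(generate_sample(m, 5), "degenerate")
})

test_that("large samples reproduce the population correlation structure", {
  m <- one_factor_model(rep(0.4, 4))
  x <- generate_sample(m, 100000, seed = 21)
  r <- compute_moments(x)$R
  expect_true(all(abs(r[upper.tri(r)] - 0.16) < 0.01))
  # columns have population mean 0 and variance 1
  expect_true(all(abs(colMeans(x)) < 0.02))
  expect_true(all(abs(apply(unclass(x), 2, sd) - 1) < 0.02))

  m0 <- one_factor_model(rep(0, 4))
  x0 <- generate_sample(m0, 50000, seed = 22)
  r0 <- compute_moments(x0)$R
  expect_true(all(abs(r0[upper.tri(r0)]) < 0.02))
})

test_that("mean sample covariance converges to the implied population matrix", {
  m <- one_factor_model(rep(0.3, 4))
  sigma <- implied_sigma(m)
  n <- 200; reps <- 400
  acc <- matrix(0, 4, 4)
  for (r in seq_len(reps))
    acc <- acc + compute_moments(generate_sample(m, n, seed = 3000 + r))$S
  avg <- acc / reps
  # element-wise Monte Carlo SE of a covariance of unit-variance normals
  se <- sqrt((1 + sigma^2) / n) / sqrt(reps)
  expect_true(all(abs(avg - sigma) < 3.5 * se))
})

test_that("moment matrices match an independent two-pass computation", {
  x <- generate_sample(one_factor_model(rep(0.4, 4)), 200, seed = 31)
  mo <- compute_moments(x)
  xm <- unclass(x)
  ctr <- sweep(xm, 2, colMeans(xm))
  S2 <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) S2[i, j] <- sum(ctr[, i] * ctr[, j]) / 199
  expect_lt(max(abs(mo$S - S2)), 1e-12)
  expect_equal(unname(diag(mo$R)), rep(1, 4))
  expect_equal(mo$R, cov2cor(mo$S))

  collinear <- cbind(c(1, 2, 3), c(2, 4, 6))
  expect_equal(compute_moments(collinear)$R[1, 2], 1.0)
  expect_error(compute_moments(cbind(c(1, 1, 1), c(1, 2, 3))),
               "zero-variance")
})

test_that("discretize maps values to the count of thresholds exceeded", {
  x <- matrix(c(-1.3, 0.7, 2.5, -0.1), 2, 2)
  expect_equal(as.vector(discretize(x, 0)), c(0L, 1L, 1L, 0L))
  expect_equal(as.vector(discretize(x, numeric(0))), rep(0L, 4))
  expect_error(discretize(x, c(0, 0)), "ascending")

  z <- generate_sample(one_factor_model(0.5, unique_variances = 0.75),
                       100000, seed = 41)
  d <- discretize(z, c(-1, 0, 1))
  props <- tabulate(d + 1L, 4) / length(d)
  expect_true(all(abs(props - c(0.1587, 0.3413, 0.3413, 0.1587)) < 0.01))
})

test_that("per-replication seeds are valid, distinct and condition-specific", {
  s1 <- replication_seed(42, 0.2, 4, 200, 1:1000)
  expect_true(all(s1 >= 0 & s1 < 2^31 - 1))
  expect_equal(length(unique(s1)), 1000)
  expect_false(replication_seed(42, 0.2, 4, 200, 1) ==
                 replication_seed(42, 0.2, 4, 300, 1))
  expect_false(replication_seed(42, 0.2, 4, 200, 1) ==
                 replication_seed(43, 0.2, 4, 200, 1))
})

test_that("condition raw data files carry the CASE column", {
  dir <- withr::local_tempdir()
  path <- write_condition_data(sim_condition(0.2, 4, 50, 3), dir,
                               master_seed = 7)
  expect_true(file.exists(path))
  expect_match(basename(path), "^N50L020_p4\\.csv$")
  d <- read.csv(path)
  expect_equal(names(d), c("CASE", "X1", "X2", "X3", "X4"))
  expect_equal(nrow(d), 150)
  expect_equal(unique(d$CASE), 1:3)
})
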