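test_that("correlation coefficient follows the exponential decay law", {
  expect_equal(correlation_coefficient(30, 30), exp(-1))
  expect_equal(correlation_coefficient(0, 30), 1)
  expect_equal(correlation_coefficient(30, Inf), 1)
  # monotone: decreasing in dt, increasing in tau
  dts <- seq(0, 300, by = 10)
  expect_true(all(diff(correlation_coefficient(dts, 30)) < 0))
  taus <- c(1, 10, 30, 100, 1e6)
  expect_true(all(diff(correlation_coefficient(30, taus)) > 0))
  expect_error(correlation_coefficient(30, 0), "tau")
  expect_error(correlation_coefficient(-1, 30), "dt")
})

test_that("variance law is proportional to the response and non-decreasing", {
  expect_equal(variance_function(1.0, 0.05), 0.0025)
  expect_equal(variance_function(0, 0.42), 0)
  expect_equal(variance_function(-2, 0.1), variance_function(2, 0.1))
  p <- sort(abs(rnorm(50)))
  expect_true(all(diff(variance_function(p, 0.03)) >= 0))
  # constant law ignores p
  expect_equal(variance_function(c(0, 1, 100), 0.2, "constant"), rep(0.04, 3))
  expect_error(variance_function(1, -0.1), "epsilon")
})

test_that("conditional error law matches closed form and its edge cases", {
  cn <- conditional_error_distribution(2, 1, 2, 0.5)
  expect_equal(cn$mean, 2)
  expect_equal(cn$variance, 3)
  # rho = 0: independence
  cn0 <- conditional_error_distribution(7, 1, 1.5, 0)
  expect_equal(cn0$mean, 0)
  expect_equal(cn0$variance, 1.5^2)
  # rho = 1, equal sigmas: perfect persistence
  cn1 <- conditional_error_distribution(0.3, 0.2, 0.2, 1)
  expect_equal(cn1$mean, 0.3)
  expect_equal(cn1$variance, 0)
  # sigma_prev = 0: chain restarts, mean term defined as 0
  cnz <- conditional_error_distribution(0, 0, 0.5, 0.9)
  expect_equal(cnz$mean, 0)
  expect_equal(cnz$variance, (1 - 0.81) * 0.25)
  expect_error(conditional_error_distribution(1, 1, 1, 1.2), "rho")
})

test_that("conditional law agrees with a rejection-sampling oracle", {
  s0 <- 1; s1 <- 2; rho <- 0.5; x0 <- 2
  pairs <- oracle_bivariate_rejection(2e6, s0, s1, rho, seed = 2208)
  cond <- pairs[abs(pairs[, "x0"] - x0) < 0.05, "x1"]
  expect_gt(length(cond), 300)
  cn <- conditional_error_distribution(x0, s0, s1, rho)
  # oracle sample moments bracket the closed form
  se_mean <- sd(cond) / sqrt(length(cond))
  expect_lt(abs(mean(cond) - cn$mean), 4 * se_mean)
  expect_lt(abs(var(cond) / cn$variance - 1), 4 * sqrt(2 / length(cond)))
  # full-distribution check against the package's sampler at alpha = 0.01
  set.seed(99)
  ours <- rnorm(length(cond), mean = cn$mean, sd = sqrt(cn$variance))
  expect_gt(suppressWarnings(ks.test(cond, ours))$p.value, 0.01)
})

test_that("zero error level returns the input series unchanged", {
  ideal <- timeseries(seq(0, 300, 30), cbind(a = 1:11 / 3, b = sin(1:11)))
  noisy <- superpose_error(ideal, noise_spec(0, tau = 30), seed = 5)
  expect_identical(noisy$values, ideal$values)
  expect_false(noisy$is_noisy)
})

test_that("stationary moments of the superposed error match AR(1) theory", {
  n <- 1e5
  ideal <- timeseries(seq(0, by = 30, length.out = n),
                      cbind(signal = rep(1, n)))
  noisy <- superpose_error(ideal, noise_spec(0.05, tau = 30), seed = 314)
  x <- noisy$values[, 1] - 1
  rho <- exp(-1)
  # marginal std = eps * p within 3 MC standard errors (AR(1)-corrected)
  neff <- n * (1 - rho) / (1 + rho)
  se_sd <- 0.05 * sqrt(1 / (2 * neff))
  expect_lt(abs(sd(x) - 0.05), 3 * se_sd)
  expect_lt(abs(mean(x)), 3 * 0.05 / sqrt(neff))
  # lag-k autocorrelation = rho^k within 3 standard errors, k = 1..3
  for (lag in 1:3) {
    r_emp <- cor(x[-(1:lag)], x[1:(n - lag)])
    se_r <- sqrt((1 - rho^(2 * lag)) / n) *
      sqrt((1 + rho^2) / (1 - rho^2))  # Bartlett-type inflation
    expect_lt(abs(r_emp - rho^lag), 3 * se_r)
  }
  # pooled errors are normal (alpha = 0.01; parameters known); thin to every
  # 5th point so the test's independence assumption holds (rho^5 < 0.01)
  expect_gt(ks.test(x[seq(1, n, by = 5)] / 0.05, "pnorm")$p.value, 0.01)
})

test_that("no variance inflation through the recursion", {
  # many independent constant-sigma chains: per-time-point variance = sigma^2
  n_t <- 40; n_chain <- 1500
  ideal <- timeseries(seq(0, by = 30, length.out = n_t),
                      matrix(1, n_t, n_chain))
  noisy <- superpose_error(ideal, noise_spec(0.1, tau = 60), seed = 2718)
  v <- apply(noisy$values - 1, 1, var)
  se <- 0.01 * sqrt(2 / (n_chain - 1))
  expect_true(all(abs(v - 0.01) < 4.5 * se))
  expect_lt(abs(mean(v) - 0.01), 3 * se / sqrt(n_t / 2))
})

test_that("superposition is reproducible and species streams are independent", {
  ideal <- timeseries(seq(0, 600, 30), cbind(a = rep(2, 21), b = rep(5, 21)))
  sp <- noise_spec(0.02, tau = 30)
  n1 <- superpose_error(ideal, sp, seed = 7)
  n2 <- superpose_error(ideal, sp, seed = 7)
  expect_identical(n1$values, n2$values)
  expect_false(identical(superpose_error(ideal, sp, seed = 8)$values,
                         n1$values))
  # dropping column b must not perturb column a's draws
  only_a <- timeseries(ideal$time, ideal$values[, "a", drop = FALSE])
  na <- superpose_error(only_a, sp, seed = 7)
  expect_identical(na$values[, "a"], n1$values[, "a"])
})

test_that("zero-valued ideal points restart the error chain cleanly", {
  p <- c(1, 1, 0, 1, 1)
  ideal <- timeseries(seq(0, 120, 30), cbind(s = p))
  noisy <- superpose_error(ideal, noise_spec(0.1, tau = 1e9), seed = 3)
  x <- noisy$values[, 1] - p
  expect_identical(x[3], 0)       # sigma(0) = 0: error exactly zero
  expect_false(anyNA(x))          # no 0/0 propagation after the restart
})

test_that("clip-at-zero flag truncates negative readings only on request", {
  ideal <- timeseries(seq(0, by = 30, length.out = 500),
                      cbind(s = rep(0.01, 500)))
  sp <- noise_spec(0.9, tau = 30)
  raw <- superpose_error(ideal, sp, seed = 12)
  expect_true(any(raw$values < 0))  # default: negative readings survive
  clipped <- superpose_error(ideal, sp, seed = 12, clip_at_zero = TRUE)
  expect_true(all(clipped$values >= 0))
})

test_that("invalid noise inputs are rejected", {
  expect_error(noise_spec(-0.1), "epsilon")
  expect_error(noise_spec(0.1, tau = -3), "tau")
  ideal <- timeseries(seq(0, 90, 30), cbind(a = 1:4))
  noisy <- superpose_error(ideal, noise_spec(0.5), seed = 1)
  expect_error(superpose_error(noisy, noise_spec(0.5), seed = 1),
               "already noisy")
})
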