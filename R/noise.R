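#' Specification of the Gauss-Markov measurement-error process
#'
#' Bundles the three quantities that define the artificial error: the error
#' level `epsilon`, the correlation time `tau`, and the variance law mapping
#' an ideal value `p` to the error variance `sigma^2(p)`.
#'
#' Two variance laws ship:
#' * `"relative"` (default): `sigma(p) = epsilon * |p|` -- error magnitude
#'   proportional to the ideal response, so `epsilon = 0.05` means a 5%
#'   relative error;
#' * `"constant"`: `sigma(p) = epsilon` -- homoscedastic error with absolute
#'   standard deviation `epsilon` in the units of the series.
#'
#' @param epsilon error level, `>= 0`.  A fraction of the response for the
#'   relative law (0.01 = 1%), an absolute standard deviation for the
#'   constant law.
#' @param tau correlation time (s), `> 0`; `Inf` gives a perfectly persistent
#'   error.  Errors separated by much more than `tau` are effectively
#'   independent.
#' @param variance_mode `"relative"` or `"constant"`.
#' @return an object of class `isd_noise_spec`.
#' @seealso [superpose_error()], [correlation_coefficient()],
#'   [variance_function()]
#' @examples
#' noise_spec(epsilon = 0.01, tau = 30)
#' @export
noise_spec <- function(epsilon, tau = 30,
                       variance_mode = c("relative", "constant")) {
  variance_mode <- match.arg(variance_mode)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || is.na(epsilon) ||
      epsilon < 0)
    stop("epsilon must be a single non-negative number")
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau <= 0)
    stop("tau must be a single positive number (Inf allowed)")
  structure(list(epsilon = epsilon, tau = tau, variance_mode = variance_mode),
            class = "isd_noise_spec")
}

#' @export
print.isd_noise_spec <- function(x, ...) {
  cat(sprintf("<isd_noise_spec> epsilon = %g, tau = %g s, variance law: %s\n",
              x$epsilon, x$tau, x$variance_mode))
  invisible(x)
}

#' Lag correlation coefficient of the Gauss-Markov error
#'
#' The correlation between two measurement errors separated by `dt` seconds
#' decays exponentially with the correlation time: `rho = exp(-dt / tau)`.
#' On an equispaced grid this is the lag-one coefficient of the equivalent
#' AR(1) process.
#'
#' @param dt elapsed time between the two measurements (s), `>= 0`.
#' @param tau correlation time (s), `> 0` (`Inf` allowed).
#' @return `exp(-dt / tau)`, in `(0, 1]`.
#' @examples
#' correlation_coefficient(30, 30)   # exp(-1)
#' correlation_coefficient(0, 30)    # 1: no time elapsed
#' @export
correlation_coefficient <- function(dt, tau) {
  if (any(!is.finite(dt) & !is.na(dt)) || any(dt < 0, na.rm = TRUE))
    stop("dt must be non-negative and finite")
  if (any(tau <= 0, na.rm = TRUE)) stop("tau must be positive")
  exp(-dt / tau)
}

#' Error variance as a function of the ideal value
#'
#' The postulated variance law `sigma_i^2 = sigma^2(p_i)`.  The relative law
#' returns `(epsilon * |p|)^2`; the constant law returns `epsilon^2`
#' regardless of `p`.  Both are non-decreasing in `|p|`.
#'
#' @param p ideal value(s).
#' @param epsilon error level (see [noise_spec()]).
#' @param variance_mode `"relative"` or `"constant"`.
#' @return variance(s), same length as `p`.
#' @examples
#' variance_function(1.0, 0.05)  # 0.0025
#' @export
variance_function <- function(p, epsilon,
                              variance_mode = c("relative", "constant")) {
  variance_mode <- match.arg(variance_mode)
  if (any(epsilon < 0)) stop("epsilon must be non-negative")
  switch(variance_mode,
         relative = (epsilon * abs(p))^2,
         constant = rep_len(epsilon^2, length(p)))
}

#' Conditional law of the next error given the previous one
#'
#' For jointly normal zero-mean errors `(X_prev, X_curr)` with standard
#' deviations `sigma_prev`, `sigma_curr` and correlation `rho`, the law of
#' `X_curr` given `X_prev = x_prev` is normal with mean
#' `rho * (sigma_curr / sigma_prev) * x_prev` and variance
#' `(1 - rho^2) * sigma_curr^2`.  When `sigma_prev = 0` the previous error is
#' almost surely 0 and the mean term is defined as 0 (the chain restarts).
#'
#' @param x_prev realised previous error.
#' @param sigma_prev,sigma_curr standard deviations, `>= 0`.
#' @param rho correlation coefficient, `|rho| <= 1`.
#' @return an object of class `isd_conditional_normal`: list with `mean` and
#'   `variance`.
#' @examples
#' conditional_error_distribution(2, 1, 2, 0.5)  # mean 2, variance 3
#' @export
conditional_error_distribution <- function(x_prev, sigma_prev, sigma_curr,
                                           rho) {
  if (abs(rho) > 1) stop("|rho| must not exceed 1")
  if (sigma_prev < 0 || sigma_curr < 0)
    stop("standard deviations must be non-negative")
  mu <- if (sigma_prev == 0) 0 else rho * (sigma_curr / sigma_prev) * x_prev
  structure(list(mean = mu, variance = (1 - rho^2) * sigma_curr^2),
            class = "isd_conditional_normal")
}

#' @export
print.isd_conditional_normal <- function(x, ...) {
  cat(sprintf("<conditional normal> mean = %g, variance = %g\n",
              x$mean, x$variance))
  invisible(x)
}

# Draw one realisation of the Gauss-Markov error along a sigma profile.
# x_1 ~ N(0, sigma_1^2); x_i | x_{i-1} ~ N(rho (sigma_i/sigma_{i-1}) x_{i-1},
# (1 - rho^2) sigma_i^2), with the mean term zeroed after a sigma = 0 point.
# Consumes exactly length(sigma) standard-normal draws from the current RNG
# stream.
gauss_markov_draw <- function(sigma, rho) {
  n <- length(sigma)
  z <- rnorm(n)
  if (all(sigma > 0)) {
    # scaled chain y_i = x_i / sigma_i is a standard AR(1) process
    y <- c(z[1L], sqrt(1 - rho^2) * z[-1L])
    if (n > 1L && rho != 0)
      y <- as.numeric(stats::filter(y, rho, method = "recursive"))
    return(sigma * y)
  }
  x <- numeric(n)
  x[1L] <- sigma[1L] * z[1L]
  sdc <- sqrt(1 - rho^2)
  for (i in seq_len(n)[-1L]) {
    mu <- if (sigma[i - 1L] > 0)
      rho * (sigma[i] / sigma[i - 1L]) * x[i - 1L] else 0
    x[i] <- mu + sdc * sigma[i] * z[i]
  }
  x
}

#' Superpose Gauss-Markov measurement error on an ideal time series
#'
#' Turns a model-calculated series `p_i` into artificial measurements
#' `M_i = p_i + X_i`, where the errors `X_i` are zero-mean normal with
#' variance `sigma^2(p_i)` and exponential correlation decay
#' `rho = exp(-dt / tau)` between consecutive samples.  Each species column
#' receives an independent error process drawn from its own seeded
#' sub-stream, so adding or removing a species never changes the draws of
#' the others.
#'
#' @param ideal an ideal [timeseries()] (`is_noisy = FALSE`).
#' @param spec an [noise_spec()].
#' @param seed integer base seed; the per-species streams are derived from it
#'   with [derive_seed()].
#' @param clip_at_zero if `TRUE`, negative noisy values are clipped to 0.
#'   Default `FALSE`: a measurement error may legitimately produce a negative
#'   reading.
#' @return a noisy `isd_timeseries` on the same grid.
#' @examples
#' ideal <- timeseries(seq(0, 300, 30), cbind(signal = rep(1, 11)))
#' noisy <- superpose_error(ideal, noise_spec(0.05, tau = 30), seed = 1)
#' @export
superpose_error <- function(ideal, spec, seed, clip_at_zero = FALSE) {
  if (!inherits(ideal, "isd_timeseries")) stop("ideal must be an isd_timeseries")
  if (!inherits(spec, "isd_noise_spec")) stop("spec must be an isd_noise_spec")
  if (isTRUE(ideal$is_noisy))
    stop("input series is already noisy; superpose on ideal series only")
  n <- nrow(ideal$values)
  rho <- if (is.na(ideal$dt)) 1 else correlation_coefficient(ideal$dt, spec$tau)
  out <- ideal$values
  for (s in seq_along(ideal$species)) {
    p <- ideal$values[, s]
    sigma <- sqrt(variance_function(p, spec$epsilon, spec$variance_mode))
    set.seed(derive_seed(seed, s))
    out[, s] <- p + gauss_markov_draw(sigma, rho)
  }
  if (clip_at_zero) out[out < 0] <- 0
  timeseries(ideal$time, out, ideal$species, is_noisy = spec$epsilon > 0)
}
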