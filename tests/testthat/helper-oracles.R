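# Independent oracles used across the test files.  These deliberately do not
# call the package's rate or noise routines: the kinetics oracle re-derives
# the mass-action balances by hand and integrates with classical fixed-step
# RK4; the conditional-law oracle rejection-samples the bivariate normal
# density directly.

# Hand-coded derivative of the semi-batch transesterification balance.
# State order: TG, DG, MG, GL, MeOH, E1, E2, E3.
oracle_deriv <- function(y, k, inv_tau, feed) {
  f1 <- k[1] * y[1] * y[5] - k[2] * y[2] * y[6]
  f2 <- k[3] * y[2] * y[5] - k[4] * y[3] * y[7]
  f3 <- k[5] * y[3] * y[5] - k[6] * y[4] * y[8]
  c(-f1, f1 - f2, f2 - f3, f3, -f1 - f2 - f3, f1, f2, f3) +
    inv_tau * (feed - y)
}

# Classical fixed-step fourth-order Runge-Kutta integration, sampled on an
# output grid that is a multiple of the internal step.
oracle_rk4 <- function(y0, k, inv_tau, feed, t_end, dt_out, substeps = 100) {
  h <- dt_out / substeps
  times <- seq(0, t_end, by = dt_out)
  out <- matrix(NA_real_, nrow = length(times), ncol = length(y0))
  out[1, ] <- y <- y0
  for (i in seq_along(times)[-1]) {
    for (s in seq_len(substeps)) {
      k1 <- oracle_deriv(y, k, inv_tau, feed)
      k2 <- oracle_deriv(y + h / 2 * k1, k, inv_tau, feed)
      k3 <- oracle_deriv(y + h / 2 * k2, k, inv_tau, feed)
      k4 <- oracle_deriv(y + h * k3, k, inv_tau, feed)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    out[i, ] <- y
  }
  list(time = times, values = out)
}

# Rejection sampler for the zero-mean bivariate normal (x0, x1) with
# standard deviations s0, s1 and correlation rho, built directly from the
# joint density.  Returns accepted pairs.
oracle_bivariate_rejection <- function(n_prop, s0, s1, rho, seed) {
  set.seed(seed)
  x0 <- runif(n_prop, -5 * s0, 5 * s0)
  x1 <- runif(n_prop, -5 * s1, 5 * s1)
  q <- (x0^2 / s0^2 + x1^2 / s1^2 - 2 * rho * x0 * x1 / (s0 * s1)) /
    (1 - rho^2)
  dens_ratio <- exp(-q / 2)          # density / density-at-mode
  keep <- runif(n_prop) < dens_ratio
  cbind(x0 = x0[keep], x1 = x1[keep])
}

# Small helper: the four default residence-time experiments (optionally at a
# reduced horizon for speed) simulated at a given truth.
make_experiments <- function(truth, residence_times = c(200, 500, 1000, 2000),
                             t_end = 3000, noise = NULL, seed = 1, ...) {
  conds <- default_conditions(residence_times, t_end = t_end, ...)
  series <- lapply(conds, simulate_reactor, k = truth)
  if (!is.null(noise))
    series <- lapply(seq_along(series), function(i)
      superpose_error(series[[i]], noise, seed = derive_seed(seed, i)))
  experiment_set(mapply(experiment, conds, series, SIMPLIFY = FALSE))
}
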