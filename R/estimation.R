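#' Bundle experiments sharing one set of rate constants
#'
#' An experiment is a reactor specification paired with the (ideal or noisy)
#' time series observed under it.  A typical set holds the four residence
#' times 200, 500, 1000 and 2000 s.
#'
#' @param ... one or more objects built with [experiment()], or a single
#'   list of them.
#' @return an object of class `isd_experiment_set`.
#' @export
experiment_set <- function(...) {
  exps <- list(...)
  if (length(exps) == 1L && is.list(exps[[1L]]) &&
      !inherits(exps[[1L]], "isd_experiment"))
    exps <- exps[[1L]]
  if (!length(exps)) stop("at least one experiment is required")
  for (e in exps) {
    if (!inherits(e, "isd_experiment"))
      stop("arguments must be built with experiment()")
  }
  structure(exps, class = "isd_experiment_set")
}

#' @rdname experiment_set
#' @param spec an [reactor_spec()].
#' @param series the observed [timeseries()] on that spec's grid.
#' @export
experiment <- function(spec, series) {
  if (!inherits(spec, "isd_reactor_spec")) stop("spec must be an isd_reactor_spec")
  if (!inherits(series, "isd_timeseries")) stop("series must be an isd_timeseries")
  grid <- seq(0, spec$t_end, by = spec$dt)
  if (length(series$time) != length(grid) ||
      any(abs(series$time - grid) > 1e-9))
    stop("series grid does not match the reactor spec (t = 0..t_end by dt)")
  structure(list(spec = spec, series = series), class = "isd_experiment")
}

#' Residual vector of an experiment set at trial rate constants
#'
#' Concatenates, over experiments, time points and species, the differences
#' `observed - simulated`, where the simulation is run at the trial `k` on
#' each experiment's own grid.  With `weighting = "none"` the raw
#' differences are returned; with `weighting = "relative"` each difference
#' is divided by `max(|observed|, floor)`, matching a measurement error
#' proportional to the response.  If the simulation fails at a trial `k`, a
#' large constant penalty residual is returned (with a warning) so that
#' optimizers back away from the infeasible region.
#'
#' @param experiments an [experiment_set()].
#' @param k trial [rate_constants()].
#' @param weighting `"none"` (raw differences) or `"relative"`.
#' @param floor lower bound on the relative-weighting denominator (mol/L),
#'   guarding the near-zero responses at early times.
#' @return numeric vector of length `sum over experiments of n_times * 8`.
#' @export
residuals_vector <- function(experiments, k,
                             weighting = c("none", "relative"),
                             floor = 1e-4) {
  weighting <- match.arg(weighting)
  if (!inherits(experiments, "isd_experiment_set"))
    stop("experiments must be an isd_experiment_set")
  res <- lapply(experiments, function(e) {
    n <- length(e$series$time) * length(e$series$species)
    sim <- tryCatch(suppressWarnings(simulate_reactor(e$spec, k)),
                    error = function(err) NULL)
    if (is.null(sim)) {
      warning("simulation failed at trial k = ",
              paste(signif(unclass(k), 4), collapse = ", "),
              "; penalty residuals used", call. = FALSE)
      return(rep(1e6, n))
    }
    d <- e$series$values - sim$values
    if (weighting == "relative")
      d <- d / pmax(abs(e$series$values), floor)
    as.numeric(d)
  })
  unlist(res, use.names = FALSE)
}

# Residual function over log-k shared by all starts; guards against
# overflowing exp() during line searches.
logk_residuals <- function(logk, experiments, weighting, floor, n_obs) {
  k <- exp(logk)
  if (any(!is.finite(k)) || any(k <= 0)) return(rep(1e6, n_obs))
  residuals_vector(experiments, rate_constants(k), weighting, floor)
}

#' Estimate the six rate constants by nonlinear least squares
#'
#' Minimises the sum of squared residuals of [residuals_vector()] over
#' `log(k)` (positivity by construction) with the Levenberg-Marquardt
#' algorithm.  The default relative weighting matches an error proportional
#' to the response and keeps the small-concentration species (which carry
#' most of the information on the reverse constants) on an equal footing
#' with the dominant triglyceride signal.
#'
#' The finite-difference Jacobian uses a relative step of about 1e-3
#' (`epsfcn = 1e-6`): the residuals carry numerical noise of order the ODE
#' solver tolerance, so steps near sqrt(machine epsilon) would differentiate
#' that noise instead of the model.
#'
#' The fit starts at `init`; if that start fails to converge, up to
#' `n_starts - 1` further starts are drawn log-uniformly within a factor 10
#' of `init` (seeded, reproducible).  Among converged starts the lowest sum
#' of squares wins; ties are broken by the lowest start index.
#'
#' @param experiments an [experiment_set()].
#' @param init initial [rate_constants()] guess.
#' @param seed integer seed for the multi-start perturbations.
#' @param n_starts maximum number of starts (default 5).
#' @param weighting,floor passed to [residuals_vector()]; default
#'   `"relative"`.
#' @param max_iter maximum Levenberg-Marquardt iterations per start.
#' @param tol convergence tolerance on the relative sum-of-squares
#'   reduction, the relative step size and the gradient orthogonality.
#' @param all_starts if `TRUE`, run every start regardless of convergence
#'   and additionally report `identifiable`: do all converged starts whose
#'   ssq ties the best (within 0.1%) agree on `k_hat` to 1e-4 relative?
#' @return an object of class `isd_fit_result`: list with `k_hat`
#'   ([rate_constants()]), `ssq`, `converged`, `n_iterations`, `init_used`,
#'   `start_index`, `ssq_trace`, `message`; with `all_starts = TRUE` also
#'   `identifiable` and the per-start list `starts`.
#' @examples
#' \donttest{
#' truth <- default_rate_constants()
#' spec <- reactor_spec(2000)
#' es <- experiment_set(experiment(spec, simulate_reactor(spec, truth)))
#' fit <- fit_rate_constants(es, init = truth)
#' }
#' @export
fit_rate_constants <- function(experiments, init, seed = 1L, n_starts = 5L,
                               weighting = c("relative", "none"),
                               floor = 1e-4, max_iter = 500L, tol = 1e-10,
                               all_starts = FALSE) {
  weighting <- match.arg(weighting)
  if (!inherits(experiments, "isd_experiment_set"))
    stop("experiments must be an isd_experiment_set")
  init <- rate_constants(init)
  n_obs <- sum(vapply(experiments, function(e) length(e$series$values),
                      numeric(1)))
  ctrl <- minpack.lm::nls.lm.control(maxiter = max_iter, ftol = tol,
                                     ptol = tol, gtol = tol, epsfcn = 1e-6)
  one_start <- function(logk0) {
    fit <- minpack.lm::nls.lm(par = logk0, fn = logk_residuals,
                              experiments = experiments,
                              weighting = weighting, floor = floor,
                              n_obs = n_obs, control = ctrl)
    list(k_hat = rate_constants(exp(fit$par)),
         ssq = fit$deviance,
         converged = fit$info %in% 1:4,
         n_iterations = fit$niter,
         # accepted iterations only; the trailing rsstrace slot may hold a
         # rejected trial step
         ssq_trace = c(fit$rsstrace[seq_len(fit$niter)], fit$deviance),
         message = fit$message)
  }

  best <- NULL
  starts <- list()
  for (s in seq_len(max(1L, n_starts))) {
    logk0 <- if (s == 1L) log(unclass(init)) else {
      set.seed(derive_seed(seed, s))
      # log-uniform within a factor 10 of init
      log(unclass(init)) + stats::runif(6L, -log(10), log(10))
    }
    res <- one_start(logk0)
    res$init_used <- rate_constants(exp(logk0))
    res$start_index <- s
    starts[[s]] <- res
    if (is.null(best) ||
        (res$converged && (!best$converged || res$ssq < best$ssq - 1e-12)))
      best <- res
    if (best$converged && !all_starts) break  # extra starts only on failure
  }
  if (all_starts) {
    conv <- Filter(function(r) r$converged, starts)
    tied <- Filter(function(r) r$ssq <= best$ssq * 1.001 + 1e-12, conv)
    best$identifiable <- length(tied) > 0L &&
      all(vapply(tied, function(r)
        max(abs(unclass(r$k_hat) / unclass(best$k_hat) - 1)) < 1e-4,
        logical(1)))
    best$starts <- starts
  }
  class(best) <- "isd_fit_result"
  best
}

#' @export
print.isd_fit_result <- function(x, ...) {
  cat(sprintf("<isd_fit_result> %s after %d iterations (start %d)\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations, x$start_index))
  print(signif(unclass(x$k_hat), 6))
  cat(sprintf("  ssq = %g\n", x$ssq))
  invisible(x)
}
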