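#' Configuration of a Monte-Carlo parameter-recovery study
#'
#' Defines the generating truth, the experimental conditions (one reactor
#' spec per residence time), the error levels of the relative noise law, the
#' correlation time, the number of replicates per level and the base seed
#' from which all randomness flows.
#'
#' @param truth generating [rate_constants()].
#' @param conditions list of [reactor_spec()] objects; default the four
#'   residence times 200, 500, 1000 and 2000 s at the default feed.
#' @param error_levels relative error levels as fractions, non-negative and
#'   sorted ascending; default `c(0, 0.01, 0.025, 0.05, 0.075, 0.10)`.
#' @param tau correlation time (s) of the error process; default 30.
#' @param n_replicates replicates per error level; default 100.
#' @param base_seed integer base seed.
#' @param init_at_truth if `TRUE` (default) fits are initialised at the
#'   generating truth, so the study measures estimator spread rather than
#'   optimizer robustness.  If `FALSE`, each replicate's init is perturbed
#'   log-uniformly within a factor 10 of the truth.
#' @return an object of class `isd_study_config`.
#' @export
study_config <- function(truth = default_rate_constants(),
                         conditions = default_conditions(),
                         error_levels = c(0, 0.01, 0.025, 0.05, 0.075, 0.10),
                         tau = 30,
                         n_replicates = 100L,
                         base_seed = 1L,
                         init_at_truth = TRUE) {
  truth <- rate_constants(truth)
  if (!is.list(conditions) || !length(conditions) ||
      !all(vapply(conditions, inherits, logical(1), "isd_reactor_spec")))
    stop("conditions must be a non-empty list of reactor_spec objects")
  if (any(error_levels < 0) || is.unsorted(error_levels))
    stop("error_levels must be non-negative and sorted ascending")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  structure(list(truth = truth, conditions = conditions,
                 error_levels = as.numeric(error_levels), tau = tau,
                 n_replicates = as.integer(n_replicates),
                 base_seed = as.integer(base_seed),
                 init_at_truth = isTRUE(init_at_truth)),
            class = "isd_study_config")
}

#' Default experimental conditions: four residence times
#'
#' @param residence_times residence times (s); default
#'   `c(200, 500, 1000, 2000)`.
#' @param ... passed to [reactor_spec()] (e.g. `c_meoh0`).
#' @return list of [reactor_spec()] objects.
#' @export
default_conditions <- function(residence_times = c(200, 500, 1000, 2000),
                               ...) {
  lapply(residence_times, reactor_spec, ...)
}

#' Summarise replicate fits into per-parameter mean and spread
#'
#' Sample mean and sample standard deviation (n - 1 denominator) of each
#' rate constant over the *converged* fits only; non-converged fits are
#' dropped and counted.
#'
#' @param fits list of [fit_rate_constants()] results.
#' @return data frame with columns `k_index`, `mean`, `sd`, `n_converged`
#'   (`sd` is `NA` for a single converged fit).
#' @export
summarize_replicates <- function(fits) {
  if (!length(fits)) stop("at least one fit is required")
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(conv)) stop("no replicate fit converged")
  K <- do.call(rbind, lapply(fits[conv], function(f) unclass(f$k_hat)))
  data.frame(k_index = 1:6,
             mean = colMeans(K),
             sd = if (nrow(K) > 1L) apply(K, 2L, sd) else rep(NA_real_, 6L),
             n_converged = nrow(K),
             row.names = NULL)
}

#' Run the Monte-Carlo parameter-recovery study
#'
#' For each error level: simulate the ideal series once per condition, then
#' for each replicate superpose an independent error realisation (seed
#' derived from `(base_seed, level index, replicate index)`), fit the six
#' rate constants, and tabulate mean +/- sd of the estimates over the
#' converged fits.  At error level 0 every replicate is identical, so a
#' single fit is performed and reported with zero spread.
#'
#' @param config an [study_config()].
#' @param verbose print a progress line per error level.
#' @return an object of class `isd_study_table`: a data frame with columns
#'   `error_pct`, `k_index`, `mean`, `sd`, `n_converged`, carrying the
#'   per-level fit lists in attribute `"fits"`.
#' @export
run_recovery_study <- function(config, verbose = FALSE) {
  if (!inherits(config, "isd_study_config"))
    stop("config must be an isd_study_config")
  ideal <- lapply(config$conditions, simulate_reactor, k = config$truth)
  rows <- list()
  all_fits <- list()

  for (li in seq_along(config$error_levels)) {
    eps <- config$error_levels[li]
    nrep <- if (eps == 0) 1L else config$n_replicates
    fits <- vector("list", nrep)
    for (r in seq_len(nrep)) {
      rep_seed <- derive_seed(config$base_seed, li, r)
      series <- if (eps == 0) ideal else {
        spec <- noise_spec(eps, tau = config$tau)
        lapply(ideal, superpose_error, spec = spec, seed = rep_seed)
      }
      exps <- experiment_set(mapply(experiment, config$conditions, series,
                                    SIMPLIFY = FALSE))
      init <- if (config$init_at_truth) config$truth else {
        set.seed(derive_seed(config$base_seed, li, r, 999L))
        rate_constants(exp(log(unclass(config$truth)) +
                           stats::runif(6L, -log(10), log(10))))
      }
      fits[[r]] <- fit_rate_constants(exps, init = init,
                                      seed = derive_seed(rep_seed, 7L))
    }
    summ <- summarize_replicates(fits)
    if (eps == 0) {
      # all replicates identical by construction: zero spread, full count
      summ$sd <- 0
      summ$n_converged <- if (fits[[1L]]$converged) config$n_replicates else 0L
    }
    n_failed <- sum(!vapply(fits, function(f) isTRUE(f$converged), logical(1)))
    if (n_failed > 0L)
      message(sprintf("error level %g%%: %d/%d fits did not converge",
                      100 * eps, n_failed, nrep))
    if (verbose)
      message(sprintf("level %g%%: mean k1 = %.4f (n = %d)",
                      100 * eps, summ$mean[1L], summ$n_converged[1L]))
    rows[[li]] <- cbind(error_pct = 100 * eps, summ)
    all_fits[[li]] <- fits
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  names(all_fits) <- paste0(100 * config$error_levels, "%")
  structure(out, fits = all_fits,
            class = c("isd_study_table", "data.frame"))
}

#' @export
print.isd_study_table <- function(x, digits = 4, ...) {
  cat("<isd_study_table> mean +/- sd of fitted rate constants\n")
  for (lev in unique(x$error_pct)) {
    d <- as.data.frame(x)[x$error_pct == lev, ]
    cells <- ifelse(is.na(d$sd) | d$sd == 0,
                    sprintf("%.*g", digits, d$mean),
                    sprintf("%.*g +/- %.*g", digits, d$mean, 2, d$sd))
    cat(sprintf("  %5s%%  %s  (n = %d)\n", lev,
                paste(sprintf("k%d: %s", d$k_index, cells), collapse = "  "),
                d$n_converged[1L]))
  }
  invisible(x)
}
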