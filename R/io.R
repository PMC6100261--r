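#' Read a time series from CSV
#'
#' The dialect is a plain comma-separated file with header
#' `time_s,<name1>,<name2>,...` (for the bundled kinetic model:
#' `time_s,TG,DG,MG,GL,MeOH,E1,E2,E3`), values in mol/L, no index column.
#' Times must be strictly increasing and equispaced.
#'
#' @param path file path.
#' @param is_noisy flag to attach to the series (the file itself does not
#'   record it); default `FALSE`.
#' @return an [timeseries()].
#' @export
read_timeseries <- function(path, is_noisy = FALSE) {
  df <- tryCatch(read.csv(path, check.names = FALSE),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e)))
  if (!ncol(df) >= 2L || names(df)[1L] != "time_s")
    stop(path, ": expected header 'time_s,<species>,...'")
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) next
    parsed <- suppressWarnings(as.numeric(as.character(df[[j]])))
    row <- which(is.na(parsed) & !is.na(df[[j]]))[1L]
    stop(path, ": non-numeric value in column '", names(df)[j],
         "' at line ", if (is.na(row)) "?" else row + 1L)  # +1 for header
  }
  if (anyNA(df)) {
    line <- which(!stats::complete.cases(df))[1L] + 1L
    stop(path, ": missing cell at line ", line)
  }
  tryCatch(
    timeseries(df[[1L]], as.matrix(df[, -1L, drop = FALSE]),
               species = names(df)[-1L], is_noisy = is_noisy),
    error = function(e) stop(path, ": ", conditionMessage(e)))
}

#' Write a time series to CSV
#'
#' Inverse of [read_timeseries()]; the round trip reproduces values to
#' better than 1e-12 relative (times and names exactly).
#'
#' @param series an [timeseries()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(series, path) {
  if (!inherits(series, "isd_timeseries"))
    stop("series must be an isd_timeseries")
  df <- as.data.frame(series)
  # 17 significant digits: lossless for doubles
  df[] <- lapply(df, function(col) sprintf("%.17g", col))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration file
#'
#' A single YAML file with nested blocks:
#'
#' \preformatted{
#' kinetics:
#'   k: [0.049, 0.109, 0.211, 1.213, 2.407, 0.069]
#'   residence_times_s: [200, 500, 1000, 2000]
#'   c_tg0_M: 1.0
#'   c_meoh0_M: 0.023
#'   t_end_s: 3000
#'   dt_s: 30
#' noise:
#'   epsilon: 0.01          # or levels: [0, 0.01, ...] for a study
#'   tau_s: 30
#'   variance_mode: relative
#'   seed: 1
#' study:
#'   n_replicates: 100
#'   base_seed: 1
#' }
#'
#' @param path YAML file path.
#' @return a list with elements `truth` ([rate_constants()]), `conditions`
#'   (list of [reactor_spec()]), `noise` ([noise_spec()] or `NULL`),
#'   `levels`, `seed`, `n_replicates`, `base_seed`, plus the raw parsed
#'   config in `$raw`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  kin <- cfg$kinetics
  if (is.null(kin$k)) stop(path, ": kinetics.k (six values) is required")
  truth <- rate_constants(as.numeric(kin$k))
  rts <- kin$residence_times_s
  if (is.null(rts)) rts <- c(200, 500, 1000, 2000)
  conditions <- default_conditions(
    residence_times = as.numeric(rts),
    c_tg0 = kin$c_tg0_M %||% 1,
    c_meoh0 = kin$c_meoh0_M %||% 0.023,
    t_end = kin$t_end_s %||% 3000,
    dt = kin$dt_s %||% 30)

  noi <- cfg$noise
  tau <- noi$tau_s %||% 30
  mode <- noi$variance_mode %||% "relative"
  spec <- if (!is.null(noi$epsilon))
    noise_spec(noi$epsilon, tau = tau, variance_mode = mode) else NULL
  levels <- as.numeric(noi$levels %||% c(0, 0.01, 0.025, 0.05, 0.075, 0.10))

  list(truth = truth, conditions = conditions, noise = spec,
       tau = tau, variance_mode = mode, levels = levels,
       seed = as.integer(noi$seed %||% 1L),
       n_replicates = as.integer(cfg$study$n_replicates %||% 100L),
       base_seed = as.integer(cfg$study$base_seed %||% 1L),
       raw = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a study table to CSV
#'
#' Long format: `error_pct,k_index,mean,std,n_converged`.
#'
#' @param table an [run_recovery_study()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(table, path) {
  df <- as.data.frame(table)
  names(df)[names(df) == "sd"] <- "std"
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
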