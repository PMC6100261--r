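#' Equispaced multi-species time series
#'
#' The central data container: concentration (or any response) values sampled
#' on a strictly increasing, equispaced time grid, one column per species.
#' A series is either *ideal* (model-calculated values `p_i`) or *noisy*
#' (artificial measurements `M_i = p_i + X_i`), distinguished by `is_noisy`.
#'
#' @param time numeric vector of sampling times (s), strictly increasing and
#'   equispaced to within 1e-9 s.
#' @param values numeric matrix (or vector for a single species), one row per
#'   time point, one column per species.
#' @param species character vector of species names; defaults to the column
#'   names of `values`.
#' @param is_noisy logical flag: do the values carry superposed error?
#' @return an object of class `isd_timeseries`: a list with elements `time`,
#'   `values` (named matrix), `species`, `t0`, `dt`, `is_noisy`.
#' @examples
#' ts <- timeseries(seq(0, 90, 30), cbind(signal = c(1, 2, 3, 4)))
#' ts$dt
#' @export
timeseries <- function(time, values, species = NULL, is_noisy = FALSE) {
  time <- as.numeric(time)
  if (length(time) < 1L) stop("a time series needs at least one time point")
  if (is.vector(values)) values <- matrix(values, ncol = 1L)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("values must be numeric")
  if (nrow(values) != length(time))
    stop("values must have one row per time point (got ", nrow(values),
         " rows for ", length(time), " times)")
  if (is.null(species)) species <- colnames(values)
  if (is.null(species)) species <- paste0("V", seq_len(ncol(values)))
  if (length(species) != ncol(values))
    stop("species names do not match the number of value columns")
  colnames(values) <- species

  dt <- NA_real_
  if (length(time) > 1L) {
    steps <- diff(time)
    if (any(steps <= 0)) stop("times must be strictly increasing")
    dt <- steps[1L]
    if (any(abs(steps - dt) > 1e-9))
      stop("times must be equispaced to within 1e-9 s")
  }
  structure(
    list(time = time, values = values, species = species,
         t0 = time[1L], dt = dt, is_noisy = isTRUE(is_noisy)),
    class = "isd_timeseries"
  )
}

#' @export
print.isd_timeseries <- function(x, ...) {
  cat(sprintf("<isd_timeseries> %d points x %d species (%s), dt = %s s, %s\n",
              length(x$time), length(x$species),
              paste(x$species, collapse = ", "),
              format(x$dt), if (x$is_noisy) "noisy" else "ideal"))
  df <- as.data.frame(x)
  print(utils::head(df, 4L), ...)
  if (nrow(df) > 4L) cat("... (", nrow(df) - 4L, " more rows)\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.isd_timeseries <- function(x, ...) {
  data.frame(time_s = x$time, x$values, check.names = FALSE)
}

#' @export
dim.isd_timeseries <- function(x) dim(x$values)
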