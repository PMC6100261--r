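#' Plot a time series, optionally with noisy points over the ideal curve
#'
#' Draws the ideal series as full lines and, if supplied, the noisy
#' measurements as points, faceted by species -- the conventional way of
#' showing in-silico data scattered about the calculated response.
#'
#' @param ideal an ideal (or any) [timeseries()] drawn as lines.
#' @param noisy optional noisy [timeseries()] on the same grid, drawn as
#'   points.
#' @return a ggplot object.
#' @export
plot_timeseries <- function(ideal, noisy = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_timeseries needs the ggplot2 package")
  long <- function(ts) {
    df <- as.data.frame(ts)
    stats::reshape(df, direction = "long", varying = ts$species,
                   v.names = "conc", timevar = "species",
                   times = ts$species, idvar = "time_s")
  }
  di <- long(ideal)
  di$species <- factor(di$species, levels = ideal$species)
  p <- ggplot2::ggplot(di, ggplot2::aes(x = .data[["time_s"]],
                                        y = .data[["conc"]])) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "concentration (mol/L)")
  if (!is.null(noisy)) {
    dn <- long(noisy)
    dn$species <- factor(dn$species, levels = noisy$species)
    p <- p + ggplot2::geom_point(data = dn, size = 0.6, alpha = 0.6)
  }
  p
}
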