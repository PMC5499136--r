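# ggplot2 views of the main result types.

#' Plot triplex-site counts along chromosomes
#'
#' Bar chart of site counts per fixed-size bin, faceted by chromosome — the
#' standard way to spot triplex hot spots.
#'
#' @param bins Output of [bin_triplexes()].
#' @param bin_size The bin size used (for the x-axis scale, in bases).
#' @return A ggplot object.
#' @export
plot_bin_counts <- function(bins, bin_size = 200000L) {
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin * bin_size / 1e6, y = .data$count)) +
    ggplot2::geom_col(width = bin_size / 1e6, fill = "steelblue") +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = "Triplex sites per bin") +
    ggplot2::theme_minimal()
}

#' Plot the TFO length distribution by motif
#'
#' @param tfos Output of [detect_tfos()].
#' @return A ggplot object.
#' @export
plot_tfo_lengths <- function(tfos) {
  d <- mutate(tfos, length = .data$t_end - .data$t_start)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$length, fill = .data$motif)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "TFO length (bases)", y = "Count", fill = "Motif") +
    ggplot2::theme_minimal()
}

#' Autoplot a pipeline run (chromosome bin profile)
#'
#' @param object A `triplex_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.triplex_run <- function(object, ...) {
  plot_bin_counts(object$bins, object$config$bin_size)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
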