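# ggplot2 views of the main result types

#' @describeIn intron_coverage `autoplot()` draws the binned intron
#'   coverage in sense orientation; vertical lines mark sites passed
#'   via `sites` (a data frame with `a_pos`, e.g. planted or called
#'   sites in the profiled intron).
#' @param object A `coverage_profile`.
#' @param sites Optional data frame with an `a_pos` column.
#' @exportS3Method ggplot2::autoplot
autoplot.coverage_profile <- function(object, sites = NULL, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$sense_start,
                                       y = .data$depth)) +
    ggplot2::geom_col(width = object$bin_size, fill = "grey35") +
    ggplot2::labs(
      x = paste0("intron position (nt, sense; ", object$chrom, ":",
                 object$start, "-", object$end, " ", object$strand, ")"),
      y = "mean depth (reads/base)") +
    ggplot2::theme_minimal()
  if (!is.null(sites) && nrow(sites) > 0L) {
    xs <- vapply(sites$a_pos, function(ap) sense_offset(object, ap),
                 numeric(1))
    p <- p + ggplot2::geom_vline(xintercept = xs, colour = "red",
                                 linetype = 2)
  }
  p
}

#' Scatter plot of up- versus down-junction read counts
#'
#' The per-site counterpart of the up/down correlation analysis:
#' each point is a site; sites lacking downstream intermediates sit on
#' the x axis.
#'
#' @param calls Tibble with merged count columns.
#' @param up_col,down_col Column names (defaults `merged_up_count`,
#'   `merged_down_count`).
#' @return A ggplot object.
#' @export
plot_junction_scatter <- function(calls, up_col = "merged_up_count",
                                  down_col = "merged_down_count") {
  check_cols(calls, c(up_col, down_col), "calls")
  ggplot2::ggplot(calls, ggplot2::aes(x = .data[[up_col]],
                                      y = .data[[down_col]])) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "up-junction reads (merged)",
                  y = "down-junction reads (merged)") +
    ggplot2::theme_minimal()
}

#' Per-position base-frequency profile of a site context
#'
#' Line plot of the base frequencies across the context window of a
#' [context_stats()] result — a text-mode stand-in for a sequence
#' logo (the matrix itself can be exported for logo rendering).
#'
#' @param stats A `context_stats` object.
#' @return A ggplot object.
#' @export
plot_context_profile <- function(stats) {
  stopifnot(inherits(stats, "context_stats"))
  ggplot2::ggplot(tidy(stats),
                  ggplot2::aes(x = .data$position, y = .data$freq,
                               colour = .data$base)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position in context window (nt)",
                  y = "base frequency") +
    ggplot2::theme_minimal()
}
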