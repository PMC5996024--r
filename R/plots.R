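#' Rose plot of an angle histogram
#'
#' Draws the circular histogram as 20-degree sectors, the standard display
#' for basal-body orientation fields.  Requires ggplot2 (Suggests).
#'
#' @param hist an `angle_histogram` from [circular_histogram()], or raw
#'   angles in radians.
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
rose_plot <- function(hist, title = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("rose_plot() needs the ggplot2 package")
  if (!inherits(hist, "angle_histogram"))
    hist <- circular_histogram(hist)
  df <- data.frame(mid = hist$bin_mid_deg, count = hist$counts)
  w <- hist$bin_end_deg[1] - hist$bin_start_deg[1]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = w, colour = "grey30", fill = "steelblue",
                      linewidth = 0.3) +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 330, by = 30)) +
    ggplot2::labs(x = NULL, y = "count", title = title) +
    ggplot2::theme_minimal()
}
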