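#' Plot a phase-plot binary image
#'
#' @param object A [phase_plot()] image.
#' @param ... Unused.
#' @return A ggplot raster of the occupancy grid in amplitude coordinates.
#' @export
autoplot.phase_plot_image <- function(object, ...) {
  ext <- attr(object, "extent") %||% 1
  n <- nrow(object)
  centers <- -ext + (seq_len(n) - 0.5) * (2 * ext / n)
  d <- tibble(
    x = rep(centers, times = ncol(object)),
    y = rep(centers, each = nrow(object)),
    on = as.vector(object) == 1L
  )
  lag <- attr(object, "lag")
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$on)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "black", `TRUE` = "white"),
                               guide = "none") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = expression(s[i]),
                  y = if (is.na(lag)) "subtracted" else sprintf("s[i + %d]", lag),
                  title = if (is.na(lag)) "subtracted phase-plot image"
                          else sprintf("phase plot, lag %d", lag)) +
    ggplot2::theme_minimal()
}

#' Plot an ECG trace
#'
#' @param record An [ecg_record()].
#' @param from,to Time window in seconds (defaults to the whole record).
#' @return A ggplot line plot of amplitude against time.
#' @export
plot_ecg <- function(record, from = 0, to = NULL) {
  stopifnot(inherits(record, "ecg_record"))
  d <- as_tibble(record)
  to <- to %||% max(d$time_s)
  d <- filter(d, .data$time_s >= from, .data$time_s <= to)
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$mv)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "amplitude (mV)",
                  title = record$record_id) +
    ggplot2::theme_minimal()
}
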