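#' Double-plot style actogram of a minute-epoch series
#'
#' Tile plot of activity by clock time (x) and day (y), the standard visual
#' check of a rest-activity recording.
#'
#' @param epochs Minute-epoch data frame (`time`, `counts`).
#' @param trans Transformation applied to counts for display (default
#'   `sqrt`, which tames the burstiness of acti-counts).
#' @return A ggplot object.
#' @export
plot_actogram <- function(epochs, trans = sqrt) {
  counts <- epoch_counts(epochs)
  nd <- length(counts) %/% 1440L
  df <- tibble(
    day = rep(seq_len(nd), each = 1440L),
    minute = rep(seq.int(0L, 1439L), nd),
    activity = trans(counts[seq_len(nd * 1440L)])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$minute / 60, y = .data$day,
                                   fill = .data$activity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse(breaks = seq_len(nd)) +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6),
                                expand = c(0, 0)) +
    ggplot2::scale_fill_viridis_c(name = "activity") +
    ggplot2::labs(x = "clock time (h)", y = "day") +
    ggplot2::theme_minimal()
}

#' @rdname rar_metrics
#' @param object A `rar_metrics` object (for `autoplot`).
#' @method autoplot rar_metrics
#' @export
autoplot.rar_metrics <- function(object, ...) {
  pd <- object$per_day[object$per_day$valid, , drop = FALSE]
  df <- tidyr::pivot_longer(
    pd[, c("day", "m10", "l5")], cols = c("m10", "l5"),
    names_to = "window", values_to = "activity"
  )
  comp <- tibble(window = c("m10", "l5"), value = c(object$m10, object$l5))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$activity,
                                   colour = .data$window)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(data = comp,
                        ggplot2::aes(yintercept = .data$value,
                                     colour = .data$window),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(m10 = "#d62728", l5 = "#1f77b4"),
                                 labels = c(m10 = "M10", l5 = "L5")) +
    ggplot2::labs(
      x = "day", y = "activity (units/min)",
      title = sprintf("M10/L5 by day (composite RA = %.2f, IS = %.2f, IV = %.2f)",
                      object$ra, object$is, object$iv)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname run_study
#' @param object A `rar_study` object (for `autoplot`).
#' @method autoplot rar_study
#' @export
autoplot.rar_study <- function(object, ...) {
  cmp <- object$comparison
  long <- dplyr::bind_rows(
    tibble(variable = cmp$variable, group = object$groups[1],
           median = cmp$median_a, q1 = cmp$q1_a, q3 = cmp$q3_a),
    tibble(variable = cmp$variable, group = object$groups[2],
           median = cmp$median_b, q1 = cmp$q1_b, q3 = cmp$q3_b)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$median,
                                     ymin = .data$q1, ymax = .data$q3,
                                     colour = .data$group)) +
    ggplot2::geom_pointrange() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "median (IQR)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
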