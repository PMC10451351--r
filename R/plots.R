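#' Plot an activity budget
#'
#' Bar chart of percent time per behavior category.
#'
#' @param object A `time_budget`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot time_budget
#' @export
autoplot.time_budget <- function(object, ...) {
  df <- tidy(object)
  df$category <- factor(df$category, df$category[order(-df$pct)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = NULL, y = "% of observation time",
      title = paste0(
        "Activity budget (", attr(object, "basis"), ", n = ",
        attr(object, "n_samples"), ")"
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a wound frequency-by-severity timeline
#'
#' @param timeline A [wound_timeline()] tibble.
#' @return A ggplot (stacked bars per bin, filled by grade).
#' @export
plot_wound_timeline <- function(timeline) {
  ggplot2::ggplot(
    timeline,
    ggplot2::aes(
      x = .data$bin_start, y = .data$n,
      fill = factor(.data$grade, 1:5)
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "YlOrRd", name = "severity") +
    ggplot2::labs(x = NULL, y = "wounds") +
    ggplot2::facet_wrap(~subject) +
    ggplot2::theme_minimal()
}

#' Plot a hair-loss trajectory
#'
#' Total body hair loss over time with the significance threshold (25%)
#' drawn as a reference line.
#'
#' @param trajectory A [hairloss_trajectory()] tibble.
#' @return A ggplot.
#' @export
plot_hairloss_trajectory <- function(trajectory) {
  ggplot2::ggplot(
    trajectory,
    ggplot2::aes(x = .data$date, y = .data$total_pct)
  ) +
    ggplot2::geom_hline(yintercept = 25, linetype = "dashed", colour = "firebrick") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "% total body hair lost") +
    ggplot2::theme_minimal()
}

#' Plot a sociogram
#'
#' Renders a [sociogram_layout()]: nodes at their force-directed positions,
#' edge width proportional to the number of nights a pair were nearest
#' neighbors.
#'
#' @param layout A `sociogram`.
#' @return A ggplot.
#' @export
plot_sociogram <- function(layout) {
  nodes <- layout$nodes
  edges <- layout$edges
  if (nrow(edges) > 0) {
    edges <- edges |>
      dplyr::left_join(nodes, by = c(a = "chimp_id")) |>
      dplyr::rename(xa = "x", ya = "y") |>
      dplyr::left_join(nodes, by = c(b = "chimp_id")) |>
      dplyr::rename(xb = "x", yb = "y")
  }
  p <- ggplot2::ggplot()
  if (nrow(edges) > 0) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(
        x = .data$xa, y = .data$ya, xend = .data$xb, yend = .data$yb,
        linewidth = .data$weight
      ),
      colour = "grey60"
    ) +
      ggplot2::scale_linewidth(range = c(0.2, 2.5), name = "nights")
  }
  p +
    ggplot2::geom_point(
      data = nodes, ggplot2::aes(x = .data$x, y = .data$y),
      size = 4, colour = "steelblue"
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$chimp_id),
      vjust = -1.2, size = 3
    ) +
    ggplot2::theme_void()
}
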