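# ggplot2 views of the main result types.

#' Plot an actogram
#'
#' One row of bars per day, activity against time of day, with the dark (or
#' subjective dark) phase shaded. For multiple flies, facets by fly.
#'
#' @param data Activity tibble (one or more flies).
#' @return A ggplot object.
#' @export
plot_actogram <- function(data) {
  check_activity(data)
  df <- data %>%
    group_by(.data$fly_id) %>%
    mutate(mins = as.numeric(difftime(.data$time, first(.data$time),
                                      units = "mins")),
           day = .data$mins %/% 1440,
           tod = (.data$mins %% 1440) / 60) %>%
    ungroup()
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$tod, y = .data$count))
  if ("light" %in% names(df)) {
    shade <- df %>%
      filter(.data$light %in% NIGHT_FLAGS) %>%
      distinct(.data$fly_id, .data$day, .data$tod)
    p <- p + ggplot2::geom_tile(
      data = shade,
      ggplot2::aes(x = .data$tod, y = 0),
      height = Inf, width = 24 / 48, fill = "grey85", inherit.aes = FALSE)
  }
  p +
    ggplot2::geom_col(width = 24 / 96, fill = "grey20") +
    ggplot2::facet_grid(ggplot2::vars(.data$day), ggplot2::vars(.data$fly_id),
                        switch = "y") +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6),
                                name = "time of day (h from lights-on)") +
    ggplot2::labs(y = "activity (counts/bin)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(strip.text.y.left = ggplot2::element_text(angle = 0),
                   panel.grid.minor = ggplot2::element_blank())
}

#' Plot cumulative selection response against cumulative differential
#'
#' Points are cycles; the line through the origin has slope equal to the
#' realized heritability estimated from the records.
#'
#' @param x A `selection_experiment` or its `$cycles` tibble.
#' @param ... Passed to [realized_h2()].
#' @return A ggplot object.
#' @export
plot_selection_response <- function(x, ...) {
  cycles <- if (inherits(x, "selection_experiment")) x$cycles else as_tibble(x)
  est <- realized_h2(cycles, ...)
  ggplot2::ggplot(cycles, ggplot2::aes(x = .data$cum_S, y = .data$cum_R)) +
    ggplot2::geom_abline(slope = est$h2, intercept = 0, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "cumulative selection differential (ND units)",
                  y = "cumulative response (ND units)",
                  subtitle = sprintf("realized h² = %.1f%%", 100 * est$h2)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.selection_experiment <- function(object, ...) {
  plot_selection_response(object, ...)
}

#' Circular plot of acrophases
#'
#' Mean-vector plot of per-fly acrophases on the 24 h clock face (15 degrees
#' per hour): one segment per fly, length equal to the resultant length R.
#'
#' @param acro A tibble from [acrophase()] or [morning_evening_peaks()]
#'   (must have `mean_deg`; `R` defaults to 1).
#' @return A ggplot object.
#' @export
plot_acrophase <- function(acro) {
  if (!"R" %in% names(acro)) acro$R <- 1
  ggplot2::ggplot(acro) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$mean_deg, xend = .data$mean_deg,
                                       y = 0, yend = .data$R)) +
    ggplot2::coord_polar(start = 0, direction = 1) +
    ggplot2::scale_x_continuous(limits = c(0, 360), breaks = seq(0, 330, 30),
                                labels = sprintf("ZT%d", seq(0, 22, 2)),
                                name = NULL) +
    ggplot2::scale_y_continuous(limits = c(0, 1), name = "R") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.masking_result <- function(object, ...) {
  df <- object$groups %>%
    tidyr::pivot_longer(c("nd_ld", "nd_dd"), names_to = "regime",
                        values_to = "nd") %>%
    mutate(regime = factor(ifelse(.data$regime == "nd_ld", "LD", "DD"),
                           levels = c("LD", "DD")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$regime, y = .data$nd,
                                   group = .data$genotype,
                                   colour = .data$genotype)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(y = "mean ND ratio", x = NULL, colour = "genotype") +
    ggplot2::theme_minimal()
}
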