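#' Plot reconstructed growth curves
#'
#' Replicate ratio values (points) and their replicate means (lines) over
#' time, one facet per phylotype, coloured by treatment, on a log10 ratio
#' axis so exponential growth appears linear.
#'
#' @param curves An `arnis_curves` tibble.
#' @param phylotypes Optional subset of phylotype ids to show.
#' @param ncol Facet columns.
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(curves, phylotypes = NULL, ncol = 4) {
  df <- as_tibble(curves)
  if (!is.null(phylotypes)) df <- df |> filter(.data$phylotype_id %in% phylotypes)
  means <- curve_means(df)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$time_h, y = .data$ratio,
    colour = .data$treatment
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_line(
      data = means,
      ggplot2::aes(y = .data$ratio_mean, group = .data$treatment)
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$phylotype_id),
      scales = "free_y", ncol = ncol
    ) +
    ggplot2::labs(
      x = "time (h)", y = "internal-standard ratio",
      colour = "treatment"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.arnis_curves <- function(object, ...) plot_growth_curves(object, ...)

#' Plot the per-treatment growth-rate distribution
#'
#' Violin of the phylotype growth rates within each treatment with the
#' mean +/- SD overlaid — the bulk community view of the rate table.
#'
#' @param rates An `arnis_rates` object or rate tibble.
#' @return A ggplot object.
#' @export
plot_rate_distribution <- function(rates) {
  tbl <- as_rate_table(rates)
  summ <- bulk_rates(tbl)
  ggplot2::ggplot(tbl, ggplot2::aes(
    x = .data$treatment, y = .data$mean_mu,
    fill = .data$treatment
  )) +
    ggplot2::geom_violin(alpha = 0.5, colour = NA) +
    ggplot2::geom_pointrange(
      data = summ,
      ggplot2::aes(
        y = .data$mean_mu,
        ymin = .data$mean_mu - dplyr::coalesce(.data$sd_mu, 0),
        ymax = .data$mean_mu + dplyr::coalesce(.data$sd_mu, 0)
      ),
      show.legend = FALSE
    ) +
    ggplot2::labs(x = "treatment", y = expression(mu ~ (day^-1))) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.arnis_rates <- function(object, ...) plot_rate_distribution(object)

#' Plot the top-down vs bottom-up response plane
#'
#' Scatter of the grazer-removal fold change against the phosphate fold
#' change per phylotype, with the classification threshold drawn as
#' reference lines and points coloured by response group.
#'
#' @param records Classified records from [classify_response()].
#' @param threshold Threshold value drawn as reference lines (default 1.3).
#' @return A ggplot object.
#' @export
plot_response_plane <- function(records, threshold = 1.3) {
  t_val <- if (inherits(threshold, "threshold_spec")) threshold$value else threshold
  df <- records |> filter(
    is.finite(.data$fc_filtered_control),
    is.finite(.data$fc_phosphate_filtered)
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$fc_filtered_control,
    y = .data$fc_phosphate_filtered, colour = .data$group
  )) +
    ggplot2::geom_hline(yintercept = t_val, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = t_val, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "fold change F / C (top-down release)",
      y = "fold change F+P / F (bottom-up release)",
      colour = "group"
    ) +
    ggplot2::theme_minimal()
}
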