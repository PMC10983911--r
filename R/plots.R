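# ggplot2 visualisations for the main result types.

#' Plot a specification curve
#'
#' Ordered point estimates with across-sample confidence intervals; the
#' 25th/75th percentile selections are highlighted.
#'
#' @param object A `spec_curve_table` from [collect_estimates()].
#' @param highlight Percentiles to mark (default 0.25 and 0.75).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spec_curve_table <- function(object, highlight = c(0.25, 0.75), ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$rank)
  marks <- purrr::map_dfr(highlight, function(p) percentile_select(object, p))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$estimate)) +
    ggplot2::geom_point(size = 0.8)
  if (!all(is.na(df$ci_lower))) {
    p <- p + ggplot2::geom_linerange(
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
      linewidth = 0.3, alpha = 0.5
    )
  }
  p +
    ggplot2::geom_point(data = marks, colour = "firebrick", size = 1.8) +
    ggplot2::labs(x = "permutation (ranked by estimate)",
                  y = "summary estimate",
                  title = "Specification curve") +
    ggplot2::theme_minimal()
}

#' Plot a bootstrap stability curve
#'
#' Mean and 95% percentile interval of each in-mask median (ICC, MSBS,
#' MSWS) as a function of subsample size.
#'
#' @param object A `stability_curve` from [bootstrap_stability()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stability_curve <- function(object, ...) {
  ggplot2::ggplot(
    object$summary,
    ggplot2::aes(x = .data$n, y = .data$mean)
  ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
      alpha = 0.25
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::facet_wrap(~ .data$metric, scales = "free_y") +
    ggplot2::labs(x = "subsample size n", y = "in-mask median",
                  title = "Bootstrap stability of reliability summaries") +
    ggplot2::theme_minimal()
}

#' Plot the in-mask ICC distribution of a reliability map set
#'
#' @param object A `reliability_maps` from [voxelwise_icc()].
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reliability_maps <- function(object, bins = 40, ...) {
  df <- tidy(object)
  df <- df[is.finite(df$icc), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$icc)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::geom_vline(xintercept = median(df$icc), colour = "firebrick") +
    ggplot2::labs(
      x = sprintf("voxelwise %s", object$icc_type), y = "voxels",
      title = "In-mask ICC distribution (red: median)"
    ) +
    ggplot2::theme_minimal()
}
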