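#' Scatter plot of MCR against HI
#'
#' The canonical diagnostic for screened mixtures: MCR on the vertical axis
#' against HI on a log10 horizontal axis, one panel (colour) per non-detect
#' case, with a reference line at HI = 1. Mixtures with an undefined MCR
#' are omitted.
#'
#' @param object An `mcr_screen` tibble from [screen_mixtures()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mcr_screen <- function(object, ...) {
  d <- dplyr::filter(as_tibble(object), !is.na(.data$mcr), .data$hi > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hi, y = .data$mcr, colour = .data$nd_case)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Hazard index (HI)", y = "Maximum cumulative ratio (MCR)",
      colour = "ND treatment"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mcr_screen
#' @export
plot_mcr_hi <- function(object, ...) autoplot.mcr_screen(object, ...)

#' Centile-subgroup MCR summary plot
#'
#' Min/mean/max MCR for each HI-centile subgroup of a cohort analysis,
#' side by side for the non-detect cases: the point is the subgroup mean
#' and the bar spans the subgroup range.
#'
#' @param object An `mcr_analysis` from [run_full_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mcr_analysis <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::mutate(
      band = sprintf("%g-%gth", .data$centile_low, .data$centile_high)
    )
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = .data$band, y = .data$mean_mcr,
      ymin = .data$min_mcr, ymax = .data$max_mcr, colour = .data$nd_case
    )
  ) +
    ggplot2::geom_pointrange(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(
      x = "HI centile band", y = "MCR (min / mean / max)",
      colour = "ND treatment"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mcr_analysis
#' @export
plot_centile_mcr <- function(object, ...) autoplot.mcr_analysis(object, ...)
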