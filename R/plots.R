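#' Plot a power spectrum
#'
#' One line per source (optionally a subset), relative or absolute power
#' against frequency.
#'
#' @param object A [power_spectrum()].
#' @param sources Source indices to draw (default up to 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.power_spectrum <- function(object, sources = NULL, ...) {
  if (is.null(sources)) sources <- seq_len(min(20, nrow(object$power)))
  df <- tidy(object) |> dplyr::filter(.data$source %in% sources)
  ggplot2::ggplot(df, ggplot2::aes(.data$freq, .data$power,
                                   group = .data$source)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(
      x = "Frequency (Hz)",
      y = if (object$normalized) "Relative power" else "Power",
      title = if (is.na(object$subject_id)) NULL else object$subject_id) +
    ggplot2::theme_minimal()
}

#' Plot a Gaussian-peak/power-law fit
#'
#' Observed spectrum points over the fitting range with the fitted
#' background and full model curves.
#'
#' @param object A [fit_peak()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.peak_fit <- function(object, ...) {
  fgrid <- seq(object$fit_lo, object$fit_hi, length.out = 200)
  bg <- object$A * fgrid^(-object$B)
  full <- bg + object$C * exp(-(fgrid - object$f_p)^2 / object$delta^2)
  obs <- tibble::tibble(freq = object$freqs, power = object$power)
  curves <- tibble::tibble(
    freq = rep(fgrid, 2), power = c(bg, full),
    component = rep(c("background", "background + peak"), each = 200))
  ggplot2::ggplot(obs, ggplot2::aes(.data$freq, .data$power)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(linetype = .data$component)) +
    ggplot2::labs(x = "Frequency (Hz)", y = "Power",
                  subtitle = sprintf("f_p = %.2f Hz%s", object$f_p,
                                     if (!object$peak_present) " (no peak)"
                                     else "")) +
    ggplot2::theme_minimal()
}

#' Plot a cluster test over the source grid
#'
#' Per-source statistic map on the grid (x-y panels by z slice), with
#' sources in significant clusters outlined.
#'
#' @param object A [cluster_permutation_test()] result.
#' @param grid The [build_source_grid()] the test was run on.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cluster_test <- function(object, grid, ...) {
  stopifnot(inherits(grid, "source_grid"))
  df <- tibble::tibble(
    x = grid$positions[, 1], y = grid$positions[, 2],
    z = factor(grid$positions[, 3]),
    t = object$statistic_map,
    significant = object$sig_mask
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$t)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = dplyr::filter(df, .data$significant),
                        shape = 21, size = 2, stroke = 0.8,
                        colour = "black") +
    ggplot2::facet_wrap(~z, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient2(na.value = "grey90") +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = "t",
                  title = sprintf("%s vs %s", object$group_levels[1],
                                  object$group_levels[2])) +
    ggplot2::theme_minimal()
}

#' Plot a regression battery
#'
#' Coefficient estimates with approximate 95% intervals per criterion, one
#' panel per predictor, FDR-significant coefficients highlighted.
#'
#' @param object A [fit_battery()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.regression_battery <- function(object, ...) {
  df <- dplyr::filter(object$results, .data$term != "intercept")
  ggplot2::ggplot(df, ggplot2::aes(.data$estimate, .data$criterion,
                                   colour = .data$fdr_significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std_error,
      xmax = .data$estimate + 1.96 * .data$std_error)) +
    ggplot2::facet_wrap(~term, scales = "free_x") +
    ggplot2::labs(x = "Estimate", y = NULL,
                  colour = sprintf("FDR q = %g", object$q)) +
    ggplot2::theme_minimal()
}
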