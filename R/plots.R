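#' Plot an isochore-bias permutation result as a percentile band
#'
#' Mirrors the stacked-panel band figures: one position per isochore class,
#' a shaded band from `log(observed / p5)` to `log(observed / p95)` and a zero
#' reference line. A band entirely above (below) zero marks a statistic
#' significantly higher (lower) than chance at the 5%/95% percentiles; classes
#' with an undefined statistic are left as gaps.
#'
#' @param object An `iso_bias_result` with permutation columns.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.iso_bias_result <- function(object, ...) {
  if (!"log_obs_p5" %in% names(object)) {
    abort("Run the statistic with `n_perm > 0` before plotting.")
  }
  df <- as_tibble(object)
  df$ymin <- pmin(df$log_obs_p5, df$log_obs_p95)
  df$ymax <- pmax(df$log_obs_p5, df$log_obs_p95)
  ggplot2::ggplot(df[!is.na(df$ymin), ],
                  ggplot2::aes(x = .data$iso_class)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$ymin, ymax = .data$ymax),
                            linewidth = 4, colour = "steelblue", alpha = 0.8) +
    ggplot2::scale_x_discrete(drop = FALSE) +
    ggplot2::labs(
      x = "isochore class",
      y = expression(log[10] * "(observed / null percentile)"),
      title = attr(object, "statistic") %||% "isochore-stratified statistic"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an mDMR/DMR threshold-selection curve
#'
#' Ratio of merged to unmerged DMR counts against the p-value threshold
#' (log10 x-axis), with the analytic floor drawn when known.
#'
#' @param object An `mdmr_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mdmr_curve <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df[!is.na(df$ratio), ],
                       ggplot2::aes(x = .data$threshold, y = .data$ratio)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "p-value threshold", y = "mDMR / DMR ratio") +
    ggplot2::theme_minimal()
  fl <- attr(object, "floor")
  if (!is.null(fl)) {
    p <- p + ggplot2::geom_hline(yintercept = fl, linetype = 3, colour = "grey40")
  }
  p
}

#' Plot Monte-Carlo-Wilcoxon GEBI results
#'
#' Observed GEBI per subset with the 5th-95th percentile range of the
#' permutation null; points outside their whisker are significant.
#'
#' @param object An `mcw_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mcw_result <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df[!is.na(df$observed), ],
                  ggplot2::aes(x = .data$subset)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$p5, ymax = .data$p95),
                            colour = "grey60", linewidth = 2, alpha = 0.7) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed,
                                     colour = .data$significant), size = 2) +
    ggplot2::labs(x = NULL,
                  y = sprintf("%sGEBI",
                              if ((attr(object, "statistic") %||% "mean") == "mean")
                                "m" else "cv")) +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}
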