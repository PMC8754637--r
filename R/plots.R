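## ggplot2 views of the package's result types.

#' Plot a metagene profile
#'
#' Line plot of bin means; flank/body profiles are faceted by segment with
#' free x scales (bp for the flanks, percent for the body).
#'
#' @param object A `metagene_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metagene_profile
#' @export
autoplot.metagene_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  kind <- attr(object, "kind")
  if (identical(kind, "percent_position")) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$mean)) +
      ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
      ggplot2::labs(x = "position in gene (%)",
                    y = "mean normalized probe value") +
      ggplot2::theme_minimal()
  } else {
    df$segment <- factor(df$segment,
                         levels = c("upstream", "body", "downstream"))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$mean)) +
      ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
      ggplot2::facet_wrap(~segment, nrow = 1, scales = "free_x") +
      ggplot2::labs(x = "flank position (bp) / body position (%)",
                    y = "mean normalized coverage") +
      ggplot2::theme_minimal()
  }
}

#' Scatter plot of two occupancy signals with the Spearman correlation
#'
#' @param data Data frame with one row per gene.
#' @param x,y Signal columns (tidy evaluation); both axes are shown on the
#'   log10 scale.
#' @param top_expressed_fraction Passed to [spearman_correlation()] for the
#'   annotation.
#' @return A ggplot object annotated with Spearman's rho.
#' @export
plot_occupancy_correlation <- function(data, x, y,
                                       top_expressed_fraction = NULL) {
  st <- spearman_correlation(data, {{ x }}, {{ y }},
                             top_expressed_fraction = top_expressed_fraction)
  ggplot2::ggplot(data, ggplot2::aes(x = {{ x }}, y = {{ y }})) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(subtitle = sprintf("Spearman rho = %.2f (n = %d)",
                                     st$rho, st$n_used)) +
    ggplot2::theme_minimal()
}

#' Scatter plot of a ratio classification
#'
#' @param classified Output of [classify_ratio_groups()].
#' @return A ggplot object: one point per classified gene, coloured by
#'   group, on log10 signal axes.
#' @export
plot_ratio_classification <- function(classified) {
  df <- classified[classified$group != "unclassified", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$polii, y = .data$upf1,
                                   colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Pol II signal", y = "Upf1 signal", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a decay profile
#'
#' @param object A `decay_fit` from [decay_profile()].
#' @param ... Unused.
#' @return A ggplot object of the relative-remaining series with the fitted
#'   exponential overlaid when a half-life is defined.
#' @method autoplot decay_fit
#' @export
autoplot.decay_fit <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$relative)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(linetype = "dotted") +
    ggplot2::labs(x = "time (min)", y = "fraction remaining") +
    ggplot2::theme_minimal()
  hl <- attr(object, "half_life")
  if (is.finite(hl)) {
    slope <- attr(object, "slope")
    p <- p + ggplot2::geom_function(fun = function(t) exp(slope * t),
                                    colour = "grey50") +
      ggplot2::labs(subtitle = sprintf("half-life = %.1f min", hl))
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
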