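#' Funnel plot of effect sizes
#'
#' Effect size against standard error (inverted axis), coloured by driver
#' type; asymmetry around the apex suggests publication bias.
#'
#' @param effects Effect-size data frame with `z`, `var_z` and optionally
#'   `driver`.
#' @return A ggplot object.
#' @export
plot_funnel <- function(effects) {
  fd <- funnel_data(effects)
  ggplot2::ggplot(fd, ggplot2::aes(x = .data$z, y = .data$se,
                                   colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Effect size (Fisher z)", y = "Standard error",
                  colour = "Driver") +
    ggplot2::theme_minimal()
}

#' Forest plot of grand mean effect sizes
#'
#' @param gm A grand-means tibble (from [grand_means()] or the
#'   `grand_means` table of an [run_pipeline()] report).
#' @return A ggplot object.
#' @export
plot_forest <- function(gm) {
  gm$label <- if ("response" %in% names(gm))
    paste(gm$response, gm$group, sep = ": ") else gm$group
  ggplot2::ggplot(gm, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Grand mean effect size (Fisher z)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Intensity meta-regression scatter
#'
#' Effect sizes against standardized driver intensity, point size
#' proportional to the meta-analytic weight (inverse sampling variance),
#' faceted by driver and response.
#'
#' @param effects Effect-size data frame with `z`, `var_z`, `intensity`,
#'   `driver`, `response`.
#' @return A ggplot object.
#' @export
plot_intensity <- function(effects) {
  ggplot2::ggplot(effects, ggplot2::aes(x = .data$intensity, y = .data$z)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(size = 1 / .data$var_z), alpha = 0.5) +
    ggplot2::facet_grid(.data$response ~ .data$driver) +
    ggplot2::scale_size_continuous(guide = "none") +
    ggplot2::labs(x = "Standardized driver intensity (log10 units above criterion)",
                  y = "Effect size (Fisher z)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_forest
#' @param object A `meta_fit` object.
#' @param ... Unused.
#' @method autoplot meta_fit
#' @export
autoplot.meta_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf_low,
                                         xmax = .data$conf_high),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Coefficient (z scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Path diagram summary of a resampled SEM
#'
#' A dot-and-whisker display of the averaged standardized (where defined) and
#' unstandardized path coefficients.
#'
#' @param object A `sem_result`.
#' @param ... Unused.
#' @method autoplot sem_result
#' @export
autoplot.sem_result <- function(object, ...) {
  td <- object$paths
  td$edge <- paste(td$from, "→", td$to)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$edge)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$estimate - 1.96 * .data$se,
                                         xmax = .data$estimate + 1.96 * .data$se),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Unstandardized path coefficient", y = NULL) +
    ggplot2::theme_minimal()
}
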