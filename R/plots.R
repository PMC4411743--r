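# ggplot2 displays for the result types.

#' Plot decile odds ratios
#'
#' Odds ratio of each score decile against the first, on a log scale, with
#' Woolf confidence intervals. Degenerate deciles (zero cells) are dropped
#' from the ribbon.
#'
#' @param object A `gxe_deciles` tibble from [decile_odds_ratios()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gxe_deciles
#' @export
autoplot.gxe_deciles <- function(object, ...) {
  d <- object[is.finite(object$odds_ratio) & object$odds_ratio > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$decile),
                                  y = .data$odds_ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lower,
                                        ymax = .data$ci_upper),
                           width = 0.2, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "risk score decile",
                  y = "odds ratio vs decile 1") +
    ggplot2::theme_minimal()
}

#' Plot variance-component proportions
#'
#' @param object A `vc_fit` from [fit_univariate()].
#' @param ... Unused.
#' @return A ggplot of the estimated proportion of phenotypic variance per
#'   component with +/- 1 SE bars.
#' @method autoplot vc_fit
#' @export
autoplot.vc_fit <- function(object, ...) {
  d <- object$components
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component,
                                  y = .data$proportion)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$proportion - .data$prop_se,
                                        ymax = .data$proportion + .data$prop_se),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "proportion of phenotypic variance") +
    ggplot2::theme_minimal()
}

#' Plot the nested-model comparison
#'
#' @param object A `gxe_profile` from [fit_nested_models()].
#' @param ... Unused.
#' @return A ggplot of -log10 p-values of the three nested additions.
#' @method autoplot gxe_profile
#' @export
autoplot.gxe_profile <- function(object, ...) {
  d <- object$comparisons
  d$term <- factor(d$term, levels = d$term)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term,
                                  y = -log10(.data$p_value))) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::labs(x = "term added", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}
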