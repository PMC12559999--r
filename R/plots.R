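#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Stacked-bar view of per-branch gene-tree conflict
#'
#' One bar per species-tree internal branch showing the proportions of gene
#' trees in the five categories, the bar analogue of per-node pie charts on
#' a phylogeny.
#'
#' @param object A [tally_conflicts()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot conflict_tally
#' @export
autoplot.conflict_tally <- function(object, ...) {
  props <- conflict_proportions(object, include_missing = TRUE)
  long <- tidyr::pivot_longer(props,
                              cols = dplyr::starts_with("pct_"),
                              names_to = "category", names_prefix = "pct_",
                              values_to = "pct")
  long$category <- factor(long$category,
                          levels = c("strong_support", "weak_support",
                                     "weak_conflict", "strong_conflict",
                                     "missing"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$branch_id, y = .data$pct,
                                     fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(
      strong_support = "#1b7837", weak_support = "#a6dba0",
      weak_conflict = "#fdb863", strong_conflict = "#b2182b",
      missing = "grey80")) +
    ggplot2::labs(x = "species-tree internal branch",
                  y = "% of gene trees", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Conflict percentage vs log internode length, with the fitted line
#'
#' @param object A `loglinear_fit` from [fit_loglinear()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot loglinear_fit
#' @export
autoplot.loglinear_fit <- function(object, ...) {
  df <- tibble::tibble(x = exp(object$fit$model[["log(xs)"]]),
                       y = object$fit$model[[1L]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ log(x), se = FALSE,
                         linetype = "dashed", colour = "black") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "internode length (log scale)", y = object$response) +
    ggplot2::theme_minimal()
}

#' Dot plot of pairwise ANI values ordered along a phylogeny
#'
#' @param tbl Output of [tree_ordered_ani_table()].
#' @param threshold Optional ANI threshold drawn as a vertical reference
#'   line (default 95).
#' @return A ggplot object.
#' @export
plot_ani_dotplot <- function(tbl, threshold = 95) {
  p <- ggplot2::ggplot(tbl, ggplot2::aes(x = .data$ani, y = .data$focal)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "ANI (%)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold,
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Class fractions of the quartet classification across alpha levels
#'
#' @param object A [classify_quartets()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot quartet_classification
#' @export
autoplot.quartet_classification <- function(object, ...) {
  long <- tidyr::pivot_longer(object$summary,
                              cols = dplyr::starts_with("frac_"),
                              names_to = "class", names_prefix = "frac_",
                              values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$alpha),
                                     y = .data$fraction,
                                     fill = .data$class)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "alpha (T3 test level)", y = "fraction of quartets",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
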