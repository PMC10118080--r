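#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_hline geom_col
#'   labs theme_minimal coord_flip stat_ellipse geom_histogram geom_vline
#' @export
ggplot2::autoplot

#' Score plot of a fitted model
#'
#' @param object A `pca_model` or `opls_da`.
#' @param components Two component indices to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name score-plots
NULL

#' @rdname score-plots
#' @export
autoplot.pca_model <- function(object, components = c(1, 2), ...) {
  sc <- tidy(object)
  xi <- paste0("t", components[1])
  yi <- paste0("t", components[2])
  ggplot(sc, aes(x = .data[[xi]], y = .data[[yi]], colour = .data$class)) +
    geom_point(size = 2) +
    labs(x = sprintf("t[%d] (R2X = %.3f)", components[1],
                     object$r2x[components[1]]),
         y = sprintf("t[%d] (R2X = %.3f)", components[2],
                     object$r2x[components[2]]),
         colour = "class", title = "PCA score plot") +
    theme_minimal()
}

#' @rdname score-plots
#' @export
autoplot.opls_da <- function(object, components = c(1, 2), ...) {
  sc <- tidy(object)
  xi <- paste0("t", components[1])
  yi <- paste0("t", components[2])
  ggplot(sc, aes(x = .data[[xi]], y = .data[[yi]], colour = .data$class)) +
    geom_point(size = 2) +
    labs(x = sprintf("t[%d] (R2X = %.3f)", components[1],
                     object$r2x[components[1]]),
         y = sprintf("t[%d] (R2X = %.3f)", components[2],
                     object$r2x[components[2]]),
         colour = "class",
         title = sprintf("OPLS-DA score plot (%d+%d+0)",
                         object$n_predictive, object$n_orthogonal)) +
    theme_minimal()
}

#' Contribution plot for one class
#'
#' Bar plot of the top model-explained variable contributions of a class,
#' with the VIP threshold-passing variables highlighted.
#'
#' @param model A fitted `opls_da`.
#' @param class_label Class to profile.
#' @param n_top Number of variables displayed.
#' @param vip_threshold VIP threshold used for highlighting.
#' @return A ggplot.
#' @export
plot_contributions <- function(model, class_label, n_top = 30,
                               vip_threshold = 1.5) {
  ct <- variable_contributions(model, class_label) %>% head(n_top)
  ct$variable <- factor(ct$variable, levels = rev(ct$variable))
  ggplot(ct, aes(x = variable, y = contribution,
                 fill = vip >= vip_threshold)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "contribution (scaled units)",
         fill = paste0("VIP >= ", vip_threshold),
         title = paste("Contributions:", class_label)) +
    theme_minimal()
}

#' Permutation-test plot
#'
#' Histogram of permuted Q2 values with the observed Q2 marked.
#'
#' @param object An `opls_permutation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.opls_permutation <- function(object, ...) {
  ggplot(object$permutations, aes(x = .data$q2)) +
    geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    geom_vline(xintercept = object$observed$q2, colour = "red",
               linewidth = 0.8) +
    labs(x = "permuted Q2", y = "count",
         title = sprintf("Permutation test: p(Q2) = %.3g", object$p_q2)) +
    theme_minimal()
}
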