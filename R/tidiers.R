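#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and glance methods for fitted models
#'
#' `tidy()` on a `pca_model` or `opls_da` returns per-sample component scores
#' in long-friendly form (one row per sample, one column per component, plus
#' the class label); `what = "loadings"` and `what = "vip"` (OPLS-DA only)
#' return per-variable quantities. `glance()` returns the one-row model
#' summary statistics.
#'
#' @param x A fitted model.
#' @param what One of `"scores"`, `"loadings"`, `"vip"`.
#' @param ... Unused.
#' @name oilmarkr-tidiers
NULL

#' @rdname oilmarkr-tidiers
#' @export
tidy.pca_model <- function(x, what = c("scores", "loadings"), ...) {
  what <- match.arg(what)
  if (what == "scores") {
    out <- as_tibble(x$scores, .name_repair = ~ paste0("t", seq_along(.x)))
    out$class <- if (is.null(x$classes)) NA_character_ else x$classes
    out
  } else {
    out <- as_tibble(x$loadings,
                     .name_repair = ~ paste0("p", seq_along(.x)))
    out$variable <- rownames(x$loadings)
    out
  }
}

#' @rdname oilmarkr-tidiers
#' @export
glance.pca_model <- function(x, ...) {
  tibble(n_components = x$n_components,
         r2x_cum = tail(x$r2x_cum, 1))
}

#' @rdname oilmarkr-tidiers
#' @export
tidy.opls_da <- function(x, what = c("scores", "loadings", "vip"), ...) {
  what <- match.arg(what)
  if (what == "scores") {
    out <- as_tibble(x$scores, .name_repair = ~ paste0("t", seq_along(.x)))
    if (x$n_orthogonal > 0) {
      orth <- as_tibble(x$scores_orth,
                        .name_repair = ~ paste0("to", seq_along(.x)))
      out <- dplyr::bind_cols(out, orth)
    }
    out$class <- x$classes
    out
  } else if (what == "loadings") {
    out <- as_tibble(x$loadings, .name_repair = ~ paste0("p", seq_along(.x)))
    out$variable <- names(x$vip)
    out
  } else {
    tibble(variable = names(x$vip), vip = unname(x$vip))
  }
}

#' @rdname oilmarkr-tidiers
#' @export
glance.opls_da <- function(x, ...) {
  tibble(n_predictive = x$n_predictive, n_orthogonal = x$n_orthogonal,
         r2x_cum = x$r2x_cum, r2y = x$r2y, q2 = x$q2, s2y = x$s2y,
         see = x$see)
}
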