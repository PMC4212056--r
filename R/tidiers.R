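#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an evaluation result into curve points
#'
#' @param x A `vcp_eval`.
#' @param ... Unused.
#' @return Long tibble of curve points with columns `curve` ("roc"/"pr"),
#'   `x`, `y`, `threshold`.
#' @method tidy vcp_eval
#' @export
tidy.vcp_eval <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(curve = "roc", x = x$roc$fpr, y = x$roc$tpr,
                   threshold = x$roc$threshold),
    tibble::tibble(curve = "pr", x = x$pr$recall, y = x$pr$precision,
                   threshold = x$pr$threshold))
}

#' One-row summary of an evaluation result
#'
#' @param x A `vcp_eval`.
#' @param ... Unused.
#' @return Tibble with `auroc`, `aupr`, `n_pos`, `n_neg`.
#' @method glance vcp_eval
#' @export
glance.vcp_eval <- function(x, ...) {
  tibble::tibble(auroc = x$auroc, aupr = x$aupr,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Plot ROC and precision-recall curves of an evaluation
#'
#' @param object A `vcp_eval`.
#' @param ... Unused.
#' @return A ggplot with one facet per curve.
#' @method autoplot vcp_eval
#' @export
autoplot.vcp_eval <- function(object, ...) {
  d <- tidy(object)
  d$curve <- factor(d$curve, c("roc", "pr"),
                    c(sprintf("ROC (AUROC %.3f)", object$auroc),
                      sprintf("PR (AUPR %.3f)", object$aupr)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_step(linewidth = 0.4) +
    ggplot2::facet_wrap(~curve) +
    ggplot2::labs(x = "FPR / recall", y = "TPR / precision") +
    ggplot2::theme_minimal()
}

#' Long feature table of a pair dataset
#'
#' @param x A `pair_dataset`.
#' @param ... Unused.
#' @return Tibble with columns `s`, `t`, `label`, `element`, `count`.
#' @method tidy pair_dataset
#' @export
tidy.pair_dataset <- function(x, ...) {
  tidyr::unnest(tibble::as_tibble(x[c("s", "t", "label", "features")]),
                "features", keep_empty = FALSE)
}

#' Sparse profile of a pair as a plot-ready bar chart
#'
#' @param object A `vcp_vector`.
#' @param ... Unused.
#' @return A ggplot of element counts.
#' @method autoplot vcp_vector
#' @export
autoplot.vcp_vector <- function(object, ...) {
  pair <- attr(object, "pair")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = factor(.data$element), y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "element", y = "count",
                  title = sprintf("VCP of pair (%s, %s)", pair[1], pair[2])) +
    ggplot2::theme_minimal()
}
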