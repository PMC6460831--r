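#' Plot a per-position importance profile
#'
#' Bar chart of log10(1/p) per offset around the GT anchor, the display
#' used to justify the short prediction window: positions whose bars tower
#' over the background are the ones worth keeping.
#'
#' @param object A `chidt_importance` tibble from [position_importance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot chidt_importance
#' @export
autoplot.chidt_importance <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$offset,
                                          levels = sort(unique(.data$offset))),
                               y = .data$log10_inv_p)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "offset relative to GT", y = "log10(1/p)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot ROC and precision-recall curves
#'
#' @param object A `chidt_curves` object from [roc_pr()].
#' @param ... Unused.
#' @return A ggplot object faceting the two curves.
#' @method autoplot chidt_curves
#' @export
autoplot.chidt_curves <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(curve = sprintf("ROC (AUC %.3f)", object$auc_roc),
                   x = object$roc$fpr, y = object$roc$tpr),
    tibble::tibble(curve = sprintf("PR (AUC %.3f)", object$auc_pr),
                   x = object$pr$recall, y = object$pr$precision))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~curve, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot the rule weight structure of a fitted model
#'
#' Per-rule positive and weighted negative counts side by side; in a
#' balanced model both rows carry the same total mass.
#'
#' @param object A `chidt_model`.
#' @param max_rules Show at most this many rules, ordered by total count.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot chidt_model
#' @export
autoplot.chidt_model <- function(object, max_rules = 40, ...) {
  d <- tidy(object)
  d <- d[order(-(d$pos + d$neg_weighted)), ][seq_len(min(max_rules, nrow(d))), ]
  long <- tidyr::pivot_longer(d, c("pos", "neg_weighted"),
                              names_to = "class", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(factor(.data$rule), .data$count,
                                     fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "rule", y = "count (negatives reweighted)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
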