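# ggplot2 views of fitted objects and rankings.

#' Precision-recall curve data for a ranking
#'
#' Non-interpolated precision/recall pairs at every rank, plus the
#' interpolated precision (running maximum from high recall down).
#'
#' @param scores Tibble with `doc_id`, `score` (from [ppi_predict()]).
#' @param gold Tibble with `doc_id`, `label`.
#' @return A tibble `rank`, `recall`, `precision`, `interpolated`.
#' @export
pr_curve <- function(scores, gold) {
  assert_labels(gold)
  ranking <- dplyr::inner_join(
    scores[, c("doc_id", "score")], gold,
    by = "doc_id"
  )
  rel <- as_relevance(ranking)
  prec <- cumsum(rel) / seq_along(rel)
  tibble(
    rank = seq_along(rel),
    recall = cumsum(rel) / sum(rel),
    precision = prec,
    interpolated = rev(cummax(rev(prec)))
  )
}

#' Plot the precision-recall curve of a ranking
#'
#' @inheritParams pr_curve
#' @param interpolated Also draw the interpolated precision envelope.
#' @return A ggplot object.
#' @export
plot_pr_curve <- function(scores, gold, interpolated = TRUE) {
  curve <- pr_curve(scores, gold)
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Recall", y = "Precision",
      title = "Precision-recall curve",
      subtitle = sprintf("AP = %.4f, AUC iP/R = %.4f",
        average_precision(ranked_from_curve(curve)),
        auc_ipr(ranked_from_curve(curve))
      )
    ) +
    ggplot2::theme_minimal()
  if (interpolated) {
    p <- p + ggplot2::geom_step(
      ggplot2::aes(y = .data$interpolated),
      color = "grey40", linetype = "dashed"
    )
  }
  p
}

# Recover the relevance vector from a pr_curve tibble.
ranked_from_curve <- function(curve) {
  c(curve$recall[1] > 0, diff(curve$recall) > 0)
}

#' @describeIn huber_fit Training cost trace as a ggplot.
#' @param object A `huber_fit`.
#' @method autoplot huber_fit
#' @export
autoplot.huber_fit <- function(object, ...) {
  trace <- tibble(
    iteration = seq_along(object$cost_trace) - 1,
    cost = object$cost_trace
  )
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$iteration, y = .data$cost)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(
      x = "Iteration", y = "Cost",
      title = "Modified-Huber training cost"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn evaluate_scores Bar chart of the metric suite.
#' @param object A `ppi_metrics` tibble.
#' @method autoplot ppi_metrics
#' @export
autoplot.ppi_metrics <- function(object, ...) {
  rates <- object[!object$metric %in% c("tp", "fp", "fn", "tn"), , drop = FALSE]
  ggplot2::ggplot(
    rates,
    ggplot2::aes(x = stats::reorder(.data$metric, .data$value), y = .data$value)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Value", title = "Classification and ranking metrics") +
    ggplot2::theme_minimal()
}
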