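# Classification and ranking metrics: the full BioCreative-style suite.

#' Confusion matrix from gold and predicted labels
#'
#' @param gold,predicted Tibbles with `doc_id`, `label` columns (labels in
#'   `{+1, -1}`), or plain integer vectors aligned by position.
#' @return A list of class `confusion_matrix` with counts `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion_matrix <- function(gold, predicted) {
  if (is.data.frame(gold)) {
    gold_ids <- gold$doc_id
    pred_ids <- predicted$doc_id
    only_gold <- setdiff(gold_ids, pred_ids)
    only_pred <- setdiff(pred_ids, gold_ids)
    if (length(only_gold) > 0 || length(only_pred) > 0) {
      abort(paste0(
        "doc_id mismatch between gold and predictions; only in gold: [",
        paste(head(only_gold, 5), collapse = ", "), "], only in predictions: [",
        paste(head(only_pred, 5), collapse = ", "), "]"
      ))
    }
    g <- gold$label
    p <- predicted$label[match(gold_ids, pred_ids)]
  } else {
    stopifnot(length(gold) == length(predicted))
    g <- as.integer(gold)
    p <- as.integer(predicted)
  }
  confusion_counts(
    tp = sum(g == 1L & p == 1L), fp = sum(g == -1L & p == 1L),
    fn = sum(g == 1L & p == -1L), tn = sum(g == -1L & p == -1L)
  )
}

#' Build a confusion matrix from counts
#'
#' @param tp,fp,fn,tn Non-negative counts.
#' @return A `confusion_matrix` object.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0, tp + fp + fn + tn > 0)
  structure(
    list(tp = as.numeric(tp), fp = as.numeric(fp), fn = as.numeric(fn), tn = as.numeric(tn)),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf(
    "Confusion matrix: TP=%g FP=%g FN=%g TN=%g\n", x$tp, x$fp, x$fn, x$tn
  ))
  invisible(x)
}

rate_or_nan <- function(num, den, what) {
  if (den == 0) {
    warn(paste0(what, " undefined (zero denominator); returning NaN"))
    return(NaN)
  }
  num / den
}

#' Basic classification rates
#'
#' Accuracy `(TP+TN)/total`, specificity `TN/(TN+FP)` (true negative rate),
#' sensitivity `TP/(TP+FN)` (recall), precision `TP/(TP+FP)`. A rate with a
#' zero denominator is `NaN` with a warning.
#'
#' @param x A `confusion_matrix`.
#' @return A one-row tibble with columns `accuracy`, `specificity`,
#'   `sensitivity`, `precision`.
#' @export
basic_rates <- function(x) {
  total <- x$tp + x$fp + x$fn + x$tn
  tibble(
    accuracy = (x$tp + x$tn) / total,
    specificity = rate_or_nan(x$tn, x$tn + x$fp, "specificity"),
    sensitivity = rate_or_nan(x$tp, x$tp + x$fn, "sensitivity"),
    precision = rate_or_nan(x$tp, x$tp + x$fp, "precision")
  )
}

#' F1 score
#'
#' Harmonic mean of precision and recall, `2PR/(P+R)`; 0 when `P + R = 0`.
#'
#' @param x A `confusion_matrix`.
#' @return A value in `[0, 1]`.
#' @export
f1_score <- function(x) {
  p_den <- x$tp + x$fp
  r_den <- x$tp + x$fn
  if (p_den == 0 || r_den == 0) {
    return(0)
  }
  p <- x$tp / p_den
  r <- x$tp / r_den
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

#' Matthews correlation coefficient
#'
#' `(TP.TN - FP.FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; 0 when any factor
#' of the denominator is zero (standard convention). Stable under class
#' imbalance because it uses all four counts.
#'
#' @param x A `confusion_matrix`.
#' @return A value in `[-1, 1]`.
#' @export
mcc_score <- function(x) {
  den <- (x$tp + x$fp) * (x$tp + x$fn) * (x$tn + x$fp) * (x$tn + x$fn)
  if (den == 0) {
    return(0)
  }
  (x$tp * x$tn - x$fp * x$fn) / sqrt(den)
}

# Order a scores/labels tibble into a deterministic ranking: descending
# score, ties broken by ascending doc_id.
ranked_labels <- function(scores) {
  stopifnot(all(c("score", "label") %in% names(scores)))
  ids <- scores$doc_id %||% as.character(seq_len(nrow(scores)))
  ord <- order(-scores$score, ids)
  scores$label[ord] == 1L
}

as_relevance <- function(ranking) {
  if (is.data.frame(ranking)) {
    ranked_labels(ranking)
  } else {
    as.logical(ranking)
  }
}

#' Average precision (non-interpolated AUC P/R)
#'
#' Mean over the relevant documents of the precision at their ranks.
#'
#' @param ranking Either a logical/0-1 vector of relevance in rank order, or
#'   a tibble with `score` and `label` columns (and optionally `doc_id` for
#'   tie-breaking), ranked by descending score with ties broken by ascending
#'   `doc_id`.
#' @return A value in `(0, 1]`.
#' @export
average_precision <- function(ranking) {
  rel <- as_relevance(ranking)
  if (sum(rel) == 0) {
    abort("average precision is undefined without a relevant document")
  }
  prec_at_rank <- cumsum(rel) / seq_along(rel)
  mean(prec_at_rank[rel])
}

#' Area under the interpolated precision-recall curve
#'
#' Interpolated precision at recall `r` is the maximum precision at any
#' recall `>= r`; the area is the mean of the interpolated precision at each
#' relevant document's recall point. Always at least as large as
#' [average_precision()] on the same ranking.
#'
#' @inheritParams average_precision
#' @param trapezoid If `TRUE`, integrate the interpolated curve by the
#'   trapezoidal rule over recall instead of averaging at the positives'
#'   recall points.
#' @return A value in `(0, 1]`.
#' @export
auc_ipr <- function(ranking, trapezoid = FALSE) {
  rel <- as_relevance(ranking)
  n_pos <- sum(rel)
  if (n_pos == 0) {
    abort("AUC iP/R is undefined without a relevant document")
  }
  prec_at_rank <- cumsum(rel) / seq_along(rel)
  # interpolate: running max of precision from the bottom of the ranking up
  ip <- rev(cummax(rev(prec_at_rank)))
  ip_at_pos <- ip[rel]
  if (!trapezoid) {
    return(mean(ip_at_pos))
  }
  recall <- seq_len(n_pos) / n_pos
  sum((ip_at_pos[-1] + ip_at_pos[-n_pos]) / 2 * diff(recall)) +
    ip_at_pos[1] * recall[1]
}

#' Precision at rank n
#'
#' @inheritParams average_precision
#' @param n Rank cutoff, `1 <= n <=` ranking length.
#' @return Fraction of the top `n` documents that are relevant.
#' @export
precision_at <- function(ranking, n) {
  rel <- as_relevance(ranking)
  if (n < 1 || n > length(rel)) {
    abort(paste0("n must be between 1 and ", length(rel)))
  }
  sum(rel[seq_len(n)]) / n
}

#' Full metric suite for scored predictions
#'
#' Joins scores with gold labels and computes the complete set of
#' classification and ranking measures: confusion counts, accuracy,
#' specificity, sensitivity, precision, F1, MCC, average precision, AUC
#' iP/R, and P@100/200/300 where the list is long enough.
#'
#' @param scores Tibble with `doc_id`, `score` and predicted `label`
#'   (from [ppi_predict()]); if `label` is absent it is derived from
#'   `sign(score)` with 0 mapped to -1.
#' @param gold Tibble with `doc_id` and gold `label`.
#' @return A tibble with `metric` and `value` columns.
#' @export
evaluate_scores <- function(scores, gold) {
  assert_labels(gold)
  if (!"label" %in% names(scores)) {
    scores$label <- ifelse(scores$score > 0, 1L, -1L)
  }
  x <- confusion_matrix(gold, scores[, c("doc_id", "label")])
  ranking <- dplyr::inner_join(
    scores[, c("doc_id", "score")], gold,
    by = "doc_id"
  )
  rel <- as_relevance(ranking)
  rates <- basic_rates(x)
  out <- tibble(
    metric = c(
      "tp", "fp", "fn", "tn", "accuracy", "specificity", "sensitivity",
      "precision", "f1", "mcc", "average_precision", "auc_ipr"
    ),
    value = c(
      x$tp, x$fp, x$fn, x$tn, rates$accuracy, rates$specificity,
      rates$sensitivity, rates$precision, f1_score(x), mcc_score(x),
      average_precision(rel), auc_ipr(rel)
    )
  )
  for (n in c(100, 200, 300)) {
    if (length(rel) >= n) {
      out <- dplyr::bind_rows(
        out,
        tibble(metric = paste0("p_at_", n), value = precision_at(rel, n))
      )
    }
  }
  class(out) <- c("ppi_metrics", class(out))
  out
}

#' @export
print.ppi_metrics <- function(x, ...) {
  cat("PPI triage evaluation:\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-18s %s\n", x$metric[i], format(x$value[i], digits = 5)))
  }
  invisible(x)
}
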