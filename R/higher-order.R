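# Higher-order (conjunction) feature induction.
#
# Three steps: (1) collect the training documents the fitted classifier
# gets wrong; (2) for every unordered pair of features co-active in a
# misclassified document, sum the partial derivative of the loss with
# respect to the would-be conjunction weight (evaluated at weight zero:
# h'(z_d) * y_d per document) over those documents; (3) keep pairs occurring
# in at least `a` documents with an absolute derivative sum of at least `b`,
# append them to the vocabulary as AND features, and retrain.

#' Indices of misclassified training documents
#'
#' @param model A `huber_fit`.
#' @param vectors Training vectors (list of index vectors).
#' @param labels Gold labels in `{+1, -1}`.
#' @return Integer vector of positions where the predicted sign differs from
#'   the label.
#' @export
find_misclassified <- function(model, vectors, labels) {
  which(huber_classify(model, vectors) != as.integer(labels))
}

#' Evaluate candidate feature pairs on misclassified documents
#'
#' For each unordered pair of active features `(i, j)`, `i < j`, within each
#' misclassified document `d`, accumulates `h'(z_d) * y_d` (the gradient of
#' the document's loss with respect to a conjunction feature whose weight is
#' still zero — the pair indicator equals 1 in that document) and counts the
#' documents containing the pair.
#'
#' @param model A `huber_fit`.
#' @param vectors Training vectors.
#' @param labels Gold labels.
#' @param misclassified Optional precomputed index set (from
#'   [find_misclassified()]).
#' @return A tibble of candidates: `i`, `j`, `count`, `deriv_sum`, sorted by
#'   decreasing `abs(deriv_sum)`.
#' @export
evaluate_pairs <- function(model, vectors, labels,
                           misclassified = find_misclassified(model, vectors, labels)) {
  empty <- tibble(
    i = integer(), j = integer(), count = integer(), deriv_sum = numeric()
  )
  if (length(misclassified) == 0) {
    return(empty)
  }
  y <- as.integer(labels)
  scores <- huber_score(model, vectors[misclassified])
  acc <- new.env(parent = emptyenv())
  for (k in seq_along(misclassified)) {
    d <- misclassified[k]
    idx <- vectors[[d]]
    if (length(idx) < 2) next
    contrib <- modified_huber_deriv(y[d] * scores[k]) * y[d]
    pairs <- utils::combn(sort(idx), 2)
    keys <- paste(pairs[1, ], pairs[2, ], sep = "&")
    for (key in keys) {
      cur <- acc[[key]] %||% c(0, 0)
      acc[[key]] <- c(cur[1] + 1, cur[2] + contrib)
    }
  }
  keys <- ls(acc)
  if (length(keys) == 0) {
    return(empty)
  }
  ij <- do.call(rbind, strsplit(keys, "&", fixed = TRUE))
  vals <- do.call(rbind, mget(keys, envir = acc))
  out <- tibble(
    i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
    count = as.integer(vals[, 1]), deriv_sum = unname(vals[, 2])
  )
  out[order(-abs(out$deriv_sum), out$i, out$j), ]
}

#' Select conjunction features from evaluated pairs
#'
#' Keeps pairs with `count >= a` and `|deriv_sum| >= b` (both bounds
#' inclusive). Each selected pair becomes a feature `H|i&j`, active in a
#' document iff both constituents are active.
#'
#' @param candidates Tibble from [evaluate_pairs()].
#' @param a Minimum occurrence count (default 4).
#' @param b Minimum absolute derivative sum (default 340; its scale tracks
#'   corpus size, so smaller corpora need a smaller `b`).
#' @return The selected candidate rows with a `feature` column added.
#' @export
select_pairs <- function(candidates, a = 4, b = 340) {
  sel <- candidates[candidates$count >= a & abs(candidates$deriv_sum) >= b, ,
    drop = FALSE
  ]
  sel$feature <- paste0("H|", sel$i, "&", sel$j)
  sel
}

#' Append conjunction features to vectors and vocabulary
#'
#' Extends each document vector with the indices of the selected pairs whose
#' constituents are both active, and appends the pair features to the
#' vocabulary with family tag `H`.
#'
#' @param vectors List of index vectors.
#' @param selected Tibble from [select_pairs()].
#' @param vocabulary Optional `ppi_vocabulary` to extend.
#' @return A list with `vectors` (extended), `vocabulary` (extended or
#'   `NULL`), and `n_new` features added.
#' @export
augment_with_pairs <- function(vectors, selected, vocabulary = NULL) {
  n_base <- if (!is.null(vocabulary)) {
    max(vocabulary$index)
  } else {
    max(c(0L, unlist(vectors)))
  }
  if (nrow(selected) == 0) {
    return(list(vectors = vectors, vocabulary = vocabulary, n_new = 0L))
  }
  new_idx <- n_base + seq_len(nrow(selected))
  vectors <- lapply(vectors, function(idx) {
    hit <- (selected$i %in% idx) & (selected$j %in% idx)
    sort(c(idx, new_idx[hit]))
  })
  if (!is.null(vocabulary)) {
    add <- tibble(
      feature = selected$feature, index = new_idx,
      doc_freq = vapply(seq_len(nrow(selected)), function(r) {
        sum(vapply(vectors, function(v) new_idx[r] %in% v, logical(1)))
      }, integer(1)),
      family = "H"
    )
    vocabulary <- dplyr::bind_rows(vocabulary, add)
    class(vocabulary) <- c("ppi_vocabulary", class(tibble()))
  }
  list(vectors = vectors, vocabulary = vocabulary, n_new = nrow(selected))
}

#' One round of higher-order feature induction with retraining
#'
#' Runs the three induction steps against a fitted model and its training
#' data, then refits the classifier on the extended vectors.
#'
#' @param model A fitted `huber_fit`.
#' @param vectors,labels The training data the model was fitted on.
#' @param a,b Selection thresholds (see [select_pairs()]).
#' @param vocabulary Optional vocabulary to extend.
#' @param ... Passed on to [huber_fit()] for the refit.
#' @return A list: `model` (refit, or the input model when nothing was
#'   selected), `vectors`, `vocabulary`, `selected` (the chosen pairs) and
#'   `candidates`.
#' @export
induce_higher_order <- function(model, vectors, labels, a = 4, b = 340,
                                vocabulary = NULL, ...) {
  mis <- find_misclassified(model, vectors, labels)
  candidates <- evaluate_pairs(model, vectors, labels, mis)
  selected <- select_pairs(candidates, a = a, b = b)
  if (nrow(selected) == 0) {
    return(list(
      model = model, vectors = vectors, vocabulary = vocabulary,
      selected = selected, candidates = candidates
    ))
  }
  aug <- augment_with_pairs(vectors, selected, vocabulary)
  n_feat <- if (!is.null(aug$vocabulary)) {
    max(aug$vocabulary$index)
  } else {
    model$n_features + nrow(selected)
  }
  refit <- huber_fit(
    aug$vectors, labels, n_features = n_feat,
    lambda_prime = model$lambda_prime, ...
  )
  list(
    model = refit, vectors = aug$vectors, vocabulary = aug$vocabulary,
    selected = selected, candidates = candidates
  )
}
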