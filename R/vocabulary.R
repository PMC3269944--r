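# Feature vocabulary: document-frequency counting, the frequency cut, and
# conversion of feature sets to sparse binary vectors.

feature_family <- function(feature) {
  sub("\\|.*$", "", feature)
}

#' Fit a feature vocabulary from training feature sets
#'
#' Counts each feature's document frequency over the training corpus and
#' removes features seen in fewer than `min_doc_freq` documents (the cut
#' applies to every family alike). Survivors are indexed 1..V in
#' lexicographic order; the vocabulary is frozen afterwards — features
#' unknown at predict time are dropped.
#'
#' @param feature_sets List of per-document feature-string sets (e.g. from
#'   [corpus_features()]).
#' @param min_doc_freq Minimum document frequency to keep a feature.
#' @return A tibble of class `ppi_vocabulary`: `feature`, `index` (1..V,
#'   contiguous), `doc_freq`, `family`.
#' @export
fit_vocabulary <- function(feature_sets, min_doc_freq = 4) {
  stopifnot(min_doc_freq >= 1)
  df <- table(unlist(lapply(feature_sets, unique)))
  keep <- df[df >= min_doc_freq]
  if (length(keep) == 0) {
    abort("no features survive the document-frequency cut")
  }
  feats <- sort(names(keep))
  out <- tibble(
    feature = feats,
    index = seq_along(feats),
    doc_freq = as.integer(keep[feats]),
    family = feature_family(feats)
  )
  class(out) <- c("ppi_vocabulary", class(out))
  out
}

#' Vectorize feature sets against a frozen vocabulary
#'
#' @param feature_sets List of per-document feature-string sets, or a single
#'   character vector (one document).
#' @param vocabulary A `ppi_vocabulary` from [fit_vocabulary()].
#' @return A list of sorted integer index vectors (binary presence);
#'   out-of-vocabulary features are silently dropped, so an empty vector is
#'   legal.
#' @export
vectorize <- function(feature_sets, vocabulary) {
  if (is.character(feature_sets)) {
    feature_sets <- list(feature_sets)
  }
  lapply(feature_sets, function(fs) {
    idx <- vocabulary$index[match(unique(fs), vocabulary$feature)]
    sort(idx[!is.na(idx)])
  })
}

# Sparse model matrix (documents x features) from index vectors.
vectors_to_matrix <- function(vectors, n_features) {
  lens <- lengths(vectors)
  Matrix::sparseMatrix(
    i = rep(seq_along(vectors), lens),
    j = unlist(vectors),
    x = 1,
    dims = c(length(vectors), n_features)
  )
}

#' Write / read the vocabulary sidecar
#'
#' Tab-separated `(feature, index, doc_freq, family)`, one row per feature.
#'
#' @param vocabulary A `ppi_vocabulary`.
#' @param path File path.
#' @return `write_vocabulary()` returns `path` invisibly;
#'   `read_vocabulary()` returns the vocabulary tibble.
#' @export
write_vocabulary <- function(vocabulary, path) {
  writeLines(
    c(
      "feature\tindex\tdoc_freq\tfamily",
      paste(vocabulary$feature, vocabulary$index, vocabulary$doc_freq,
        vocabulary$family,
        sep = "\t"
      )
    ),
    path
  )
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  lines <- read_input_lines(path)[-1]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- tibble(
    feature = vapply(parts, `[[`, character(1), 1),
    index = as.integer(vapply(parts, `[[`, character(1), 2)),
    doc_freq = as.integer(vapply(parts, `[[`, character(1), 3)),
    family = vapply(parts, `[[`, character(1), 4)
  )
  class(out) <- c("ppi_vocabulary", class(out))
  out
}
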