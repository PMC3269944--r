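# End-to-end pipeline: run presets wiring gene tagging, feature extraction,
# vocabulary fitting, vectorization, Huber training and optional
# higher-order induction into train / predict / evaluate entry points.

#' Run configuration presets
#'
#' Expands one of the five submitted run configurations into a
#' [feature_config()] plus pipeline switches:
#' \itemize{
#'   \item `run1`: word unigrams + bigrams, MeSH subphrases, substrings,
#'     dependency relations (unstemmed), gene anonymization; no trigrams, no
#'     feature cut, no higher-order features.
#'   \item `run2`: `run1` trained with the additional training corpus.
#'   \item `run3`: `run1` plus word trigrams, Porter-stemmed dependency
#'     relations and the document-frequency cut (`min_doc_freq = 4`).
#'   \item `run4`: `run3` with the additional training corpus.
#'   \item `run5`: `run3` plus one round of higher-order feature induction.
#' }
#'
#' @param preset One of `"run1"` .. `"run5"`.
#' @param lambda_prime Base regularization rate (default 0.0005).
#' @param higher_order_a,higher_order_b Induction thresholds (defaults 4 and
#'   340; `b` scales with corpus size).
#' @param settings A [train_settings()].
#' @param ... Overrides forwarded to [feature_config()].
#' @return A list of class `run_config`.
#' @export
run_preset <- function(preset = c("run1", "run2", "run3", "run4", "run5"),
                       lambda_prime = 5e-4, higher_order_a = 4,
                       higher_order_b = 340, settings = train_settings(),
                       ...) {
  preset <- match.arg(preset)
  rich <- preset %in% c("run3", "run4", "run5")
  fc_args <- list(
    use_unigram = TRUE, use_bigram = TRUE, use_trigram = rich,
    use_substrings = TRUE, use_mesh = TRUE, use_dependency = TRUE,
    stem_dependency = rich, anonymize_genes = TRUE,
    min_doc_freq = if (rich) 4L else 1L
  )
  fc_args[names(list(...))] <- list(...)
  structure(
    list(
      preset = preset,
      features = do.call(feature_config, fc_args),
      use_extra_training = preset %in% c("run2", "run4"),
      higher_order = preset == "run5",
      higher_order_a = higher_order_a, higher_order_b = higher_order_b,
      lambda_prime = lambda_prime, settings = settings
    ),
    class = "run_config"
  )
}

#' Tag gene mentions over a whole corpus
#'
#' Applies the Priority Model to each document using the regex fallback
#' candidate chunker of [candidate_phrases()].
#'
#' @param model A `priority_model`.
#' @param documents Corpus tibble.
#' @return Mention tibble over the corpus.
#' @export
tag_corpus <- function(model, documents) {
  rows <- vector("list", nrow(documents))
  for (i in seq_len(nrow(documents))) {
    cand <- candidate_phrases(documents$title[i], documents$abstract[i])
    rows[[i]] <- tag_mentions(
      model, cand$sentences, cand$candidates,
      doc_id = documents$doc_id[i]
    )
  }
  dplyr::bind_rows(rows)
}

#' Train the PPI article classifier
#'
#' Full training pipeline: (optional) gene tagging, feature extraction per
#' the run configuration, vocabulary fitting with the document-frequency
#' cut, vectorization, data-derived regularization, modified-Huber training
#' and, for `run5`-style configurations, one round of higher-order feature
#' induction followed by retraining.
#'
#' @param documents Corpus tibble (see [read_corpus()]).
#' @param labels Tibble `doc_id`, `label` covering exactly the corpus ids.
#' @param parses Parse tibble; required when the configuration uses
#'   dependency features.
#' @param mentions Gene-mention tibble (e.g. gold mentions or from
#'   [tag_corpus()]); optional.
#' @param priority A fitted `priority_model` used to tag mentions when
#'   `mentions` is not supplied; optional.
#' @param config A [run_preset()] or compatible list.
#' @param extra Optional additional training data: a list with `documents`,
#'   `labels` and optionally `parses`, `mentions`, appended to the training
#'   set when the configuration requests it.
#' @return An object of class `ppi_model`: the fitted classifier,
#'   vocabulary, configuration, mentions used, and a training report
#'   (vocabulary size, cost trace, training confusion and metrics, induced
#'   pairs).
#' @export
ppi_train <- function(documents, labels, parses = NULL, mentions = NULL,
                      priority = NULL, config = run_preset("run1"),
                      extra = NULL) {
  assert_labels(labels)
  if (config$use_extra_training && !is.null(extra)) {
    documents <- dplyr::bind_rows(documents, extra$documents)
    labels <- dplyr::bind_rows(labels, extra$labels)
    if (!is.null(extra$parses)) {
      parses <- dplyr::bind_rows(parses %||% empty_parses(), extra$parses)
    }
    if (!is.null(extra$mentions) && !is.null(mentions)) {
      mentions <- dplyr::bind_rows(mentions, extra$mentions)
    }
  }
  if (!setequal(documents$doc_id, labels$doc_id)) {
    abort("corpus and label doc_ids do not match")
  }
  if (config$features$use_dependency && is.null(parses)) {
    abort("the configuration uses dependency features but no parses were given")
  }
  if (is.null(mentions) && !is.null(priority)) {
    mentions <- tag_corpus(priority, documents)
  }

  feats <- corpus_features(documents, parses, mentions, config$features)
  vocabulary <- fit_vocabulary(feats, config$features$min_doc_freq)
  vectors <- vectorize(feats, vocabulary)
  y <- labels$label[match(documents$doc_id, labels$doc_id)]

  fit <- huber_fit(
    vectors, y, n_features = max(vocabulary$index),
    lambda_prime = config$lambda_prime, settings = config$settings
  )

  selected <- tibble()
  if (isTRUE(config$higher_order)) {
    ho <- induce_higher_order(
      fit, vectors, y,
      a = config$higher_order_a, b = config$higher_order_b,
      vocabulary = vocabulary, settings = config$settings
    )
    fit <- ho$model
    vectors <- ho$vectors
    vocabulary <- ho$vocabulary
    selected <- ho$selected
  }

  pred <- huber_classify(fit, vectors)
  train_cm <- confusion_matrix(y, pred)
  train_scores <- tibble(
    doc_id = documents$doc_id, score = huber_score(fit, vectors), label = pred
  )
  report <- list(
    preset = config$preset %||% "custom",
    n_documents = nrow(documents),
    n_positive = sum(y == 1L),
    vocabulary_size = max(vocabulary$index),
    induced_pairs = nrow(selected),
    cost_trace = fit$cost_trace,
    training_confusion = train_cm,
    training_metrics = evaluate_scores(
      train_scores, tibble(doc_id = documents$doc_id, label = y)
    )
  )
  structure(
    list(
      fit = fit, vocabulary = vocabulary, config = config,
      priority = priority, selected_pairs = selected, report = report
    ),
    class = "ppi_model"
  )
}

#' @export
print.ppi_model <- function(x, ...) {
  r <- x$report
  cat(
    "PPI article classifier (", r$preset, "): ", r$n_documents,
    " training documents, ", r$vocabulary_size, " features",
    if (r$induced_pairs > 0) paste0(" (", r$induced_pairs, " induced pairs)"),
    "\n",
    sep = ""
  )
  f1 <- r$training_metrics$value[r$training_metrics$metric == "f1"]
  cat("  training F1:", format(f1, digits = 4), "\n")
  invisible(x)
}

# Re-activate induced conjunction features for out-of-sample vectors.
apply_pair_features <- function(vectors, vocabulary) {
  hrows <- vocabulary[vocabulary$family == "H", , drop = FALSE]
  if (nrow(hrows) == 0) {
    return(vectors)
  }
  ij <- do.call(rbind, strsplit(sub("^H\\|", "", hrows$feature), "&", fixed = TRUE))
  i <- as.integer(ij[, 1])
  j <- as.integer(ij[, 2])
  lapply(vectors, function(idx) {
    hit <- (i %in% idx) & (j %in% idx)
    sort(c(idx, hrows$index[hit]))
  })
}

#' Score new documents with a trained model
#'
#' Extracts features under the training configuration, vectorizes against
#' the frozen vocabulary (unknown features dropped, induced conjunctions
#' re-activated), and returns ranked scores with sign labels.
#'
#' @param object A `ppi_model`.
#' @param documents Corpus tibble.
#' @param parses,mentions As in [ppi_train()]; mentions are tagged with the
#'   stored Priority Model when available and not supplied.
#' @param ... Unused.
#' @return A tibble `doc_id`, `score`, `label`, sorted by descending score
#'   (ties by ascending `doc_id`). A document with no known features scores
#'   exactly `theta`.
#' @export
predict.ppi_model <- function(object, documents, parses = NULL,
                              mentions = NULL, ...) {
  config <- object$config
  if (config$features$use_dependency && is.null(parses)) {
    abort("the configuration uses dependency features but no parses were given")
  }
  if (is.null(mentions) && !is.null(object$priority)) {
    mentions <- tag_corpus(object$priority, documents)
  }
  feats <- corpus_features(documents, parses, mentions, config$features)
  base_vocab <- object$vocabulary[object$vocabulary$family != "H", , drop = FALSE]
  vectors <- vectorize(feats, base_vocab)
  vectors <- apply_pair_features(vectors, object$vocabulary)
  if (max(object$vocabulary$index) != object$fit$n_features) {
    abort("vocabulary and model disagree on the feature count")
  }
  scores <- huber_score(object$fit, vectors)
  out <- tibble(
    doc_id = documents$doc_id, score = scores,
    label = ifelse(scores > 0, 1L, -1L)
  )
  out[order(-out$score, out$doc_id), ]
}

#' Alias for scoring with a trained model
#'
#' @inheritParams predict.ppi_model
#' @export
ppi_predict <- function(object, documents, parses = NULL, mentions = NULL) {
  predict(object, documents, parses = parses, mentions = mentions)
}

#' Write / read scored predictions
#'
#' TSV `doc_id<TAB>score<TAB>label`, sorted by descending score.
#'
#' @param scores Tibble from [ppi_predict()].
#' @param path File path.
#' @return `write_scores()` returns `path` invisibly; `read_scores()` the
#'   tibble.
#' @export
write_scores <- function(scores, path) {
  writeLines(
    sprintf("%s\t%.17g\t%d", scores$doc_id, scores$score, scores$label),
    path
  )
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  lines <- read_input_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble(
    doc_id = vapply(parts, `[[`, character(1), 1),
    score = as.numeric(vapply(parts, `[[`, character(1), 2)),
    label = as.integer(vapply(parts, `[[`, character(1), 3))
  )
}

#' Persist / restore a trained pipeline as plain text artifacts
#'
#' Writes the classifier, vocabulary, configuration and (if present)
#' Priority Model into a directory.
#'
#' @param model A `ppi_model`.
#' @param dir Directory path (created if needed).
#' @return `ppi_save()` returns `dir` invisibly; `ppi_load()` the model.
#' @export
ppi_save <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_huber_model(model$fit, file.path(dir, "model.tsv"))
  write_vocabulary(model$vocabulary, file.path(dir, "vocabulary.tsv"))
  cfg <- model$config
  jsonlite::write_json(
    list(
      preset = cfg$preset %||% "custom",
      features = unclass(cfg$features),
      lambda_prime = cfg$lambda_prime,
      higher_order = isTRUE(cfg$higher_order),
      higher_order_a = cfg$higher_order_a, higher_order_b = cfg$higher_order_b
    ),
    file.path(dir, "config.json"),
    auto_unbox = TRUE
  )
  if (!is.null(model$priority)) {
    write_priority_model(model$priority, file.path(dir, "priority.tsv"))
  }
  invisible(dir)
}

#' @rdname ppi_save
#' @export
ppi_load <- function(dir) {
  cfg_json <- jsonlite::fromJSON(file.path(dir, "config.json"))
  fc <- do.call(feature_config, cfg_json$features)
  config <- structure(
    list(
      preset = cfg_json$preset, features = fc,
      use_extra_training = FALSE,
      higher_order = isTRUE(cfg_json$higher_order),
      higher_order_a = cfg_json$higher_order_a,
      higher_order_b = cfg_json$higher_order_b,
      lambda_prime = cfg_json$lambda_prime,
      settings = train_settings()
    ),
    class = "run_config"
  )
  priority_path <- file.path(dir, "priority.tsv")
  structure(
    list(
      fit = read_huber_model(file.path(dir, "model.tsv")),
      vocabulary = read_vocabulary(file.path(dir, "vocabulary.tsv")),
      config = config,
      priority = if (file.exists(priority_path)) {
        read_priority_model(priority_path)
      },
      selected_pairs = tibble(),
      report = list(
        preset = cfg_json$preset, n_documents = NA_integer_,
        n_positive = NA_integer_, vocabulary_size = NA_integer_,
        induced_pairs = NA_integer_, cost_trace = numeric(0),
        training_confusion = NULL, training_metrics = NULL
      )
    ),
    class = "ppi_model"
  )
}
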