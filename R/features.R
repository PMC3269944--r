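# Feature extraction: five families of binary document features, each
# namespaced by a family prefix so families can never collide:
#   W1|, W2|, W3|  word n-grams (within sentences only)
#   S|             character substrings of tokens
#   M1|, M2|       MeSH descriptor subphrases
#   D|             dependency relations, optionally stemmed / anonymized
#   H|             induced higher-order (conjunction) features

#' Feature extraction configuration
#'
#' Captures the feature-family toggles of the five submitted run
#' configurations: which word n-gram orders to use, character substrings,
#' MeSH subphrases, dependency relations with optional Porter stemming and
#' gene anonymization, and the minimum document frequency below which
#' features are cut from the vocabulary.
#'
#' @param use_unigram,use_bigram,use_trigram Word n-gram orders.
#' @param use_substrings Character k-gram features over tokens.
#' @param substring_k Substring length (default 6; six consecutive characters
#'   performed best in development).
#' @param use_mesh MeSH descriptor subphrase features.
#' @param use_dependency Dependency-relation features (requires parses).
#' @param stem_dependency Porter-stem words inside dependency relations.
#' @param anonymize_genes Replace detected gene names with `anonymous_tag`
#'   (dependent positions in relations; whole mentions in the n-gram token
#'   stream).
#' @param anonymous_tag Replacement tag, default `"PTNWORD"`.
#' @param min_doc_freq Features seen in fewer training documents are removed
#'   (default 4; 1 disables the cut).
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(use_unigram = TRUE, use_bigram = TRUE,
                           use_trigram = FALSE, use_substrings = TRUE,
                           substring_k = 6, use_mesh = TRUE,
                           use_dependency = TRUE, stem_dependency = FALSE,
                           anonymize_genes = TRUE,
                           anonymous_tag = "PTNWORD", min_doc_freq = 4) {
  stopifnot(substring_k >= 2, min_doc_freq >= 1)
  structure(
    list(
      use_unigram = use_unigram, use_bigram = use_bigram,
      use_trigram = use_trigram, use_substrings = use_substrings,
      substring_k = as.integer(substring_k), use_mesh = use_mesh,
      use_dependency = use_dependency, stem_dependency = stem_dependency,
      anonymize_genes = anonymize_genes, anonymous_tag = anonymous_tag,
      min_doc_freq = as.integer(min_doc_freq)
    ),
    class = "feature_config"
  )
}

#' Word n-gram features
#'
#' Emits `W1|t`, `W2|t1_t2`, `W3|t1_t2_t3` for the enabled orders. N-grams
#' never cross sentence boundaries: only neighboring words within a sentence
#' are combined.
#'
#' @param sentences List of per-sentence token vectors. When gene
#'   anonymization is on, mentions must already be collapsed to the
#'   anonymous tag (see [anonymize_tokens()]).
#' @param config A [feature_config()].
#' @return Character vector of feature strings (with duplicates; callers
#'   take the set).
#' @export
word_ngram_features <- function(sentences, config = feature_config()) {
  out <- character(0)
  for (toks in sentences) {
    n <- length(toks)
    if (n == 0) next
    if (config$use_unigram) {
      out <- c(out, paste0("W1|", toks))
    }
    if (config$use_bigram && n >= 2) {
      out <- c(out, paste0("W2|", toks[-n], "_", toks[-1]))
    }
    if (config$use_trigram && n >= 3) {
      out <- c(out, paste0(
        "W3|", toks[1:(n - 2)], "_", toks[2:(n - 1)], "_", toks[3:n]
      ))
    }
  }
  out
}

#' Character substring features
#'
#' All contiguous character k-grams of each lowercased token, prefixed `S|`.
#' Tokens shorter than `k` contribute the whole token as a single feature.
#' Windows never cross token boundaries.
#'
#' @param tokens Character vector of (lowercased) tokens.
#' @param k Window length, default 6.
#' @return Character vector of feature strings.
#' @export
substring_features <- function(tokens, k = 6) {
  out <- character(0)
  for (tok in tokens) {
    n <- nchar(tok)
    if (n == 0) next
    if (n <= k) {
      out <- c(out, paste0("S|", tok))
    } else {
      starts <- 1:(n - k + 1)
      out <- c(out, paste0("S|", substring(tok, starts, starts + k - 1)))
    }
  }
  out
}

#' MeSH descriptor subphrase features
#'
#' Each descriptor is lowercased and tokenized on whitespace and commas;
#' unigram (`M1|`) and bigram (`M2|`) subphrases within a descriptor are
#' emitted. Qualifiers after `/` are treated as separate descriptors.
#'
#' @param mesh_terms Character vector of raw MeSH descriptor strings.
#' @return Character vector of feature strings.
#' @export
mesh_features <- function(mesh_terms) {
  if (length(mesh_terms) == 0) {
    return(character(0))
  }
  descriptors <- unlist(strsplit(mesh_terms, "/", fixed = TRUE))
  descriptors <- trimws(descriptors)
  descriptors <- descriptors[nzchar(descriptors)]
  out <- character(0)
  for (d in descriptors) {
    toks <- regmatches(
      tolower(d), gregexpr("[[:alnum:]]+(?:-[[:alnum:]]+)*", tolower(d))
    )[[1]]
    n <- length(toks)
    if (n == 0) next
    out <- c(out, paste0("M1|", toks))
    if (n >= 2) {
      out <- c(out, paste0("M2|", toks[-n], "_", toks[-1]))
    }
  }
  out
}

#' Dependency-relation features
#'
#' One feature `D|rel(head,dep)` per relation. When gene anonymization is on,
#' a dependent word that lies inside a detected gene mention is replaced by
#' the anonymous tag; head words are never anonymized (only gene names in
#' dependent positions are replaced). When stemming is on, the Porter stemmer
#' is applied to the head and to the dependent unless it was anonymized (the
#' tag itself is never stemmed). Both words are lowercased (the tag excepted).
#'
#' @param parses Parse tibble for one document (columns `sentence_index`,
#'   `relation`, `head`, `dependent`).
#' @param mentions Gene-mention tibble for the same document (columns
#'   `sentence_index`, `text`); multi-word mentions match any of their
#'   tokens as well as the full surface.
#' @param config A [feature_config()].
#' @return Character vector of feature strings.
#' @export
dependency_features <- function(parses, mentions = NULL,
                                config = feature_config()) {
  if (is.null(parses) || nrow(parses) == 0) {
    return(character(0))
  }
  mention_sets <- mention_token_sets(mentions)
  out <- character(nrow(parses))
  for (i in seq_len(nrow(parses))) {
    rel <- parses$relation[i]
    head_w <- tolower(parses$head[i])
    dep_w <- tolower(parses$dependent[i])
    anon <- FALSE
    if (config$anonymize_genes && !is.null(mention_sets)) {
      key <- as.character(parses$sentence_index[i])
      if (dep_w %in% (mention_sets[[key]] %||% character(0))) {
        anon <- TRUE
      }
    }
    if (config$stem_dependency) {
      head_w <- porter_stem(head_w)
      if (!anon) dep_w <- porter_stem(dep_w)
    }
    if (anon) dep_w <- config$anonymous_tag
    out[i] <- paste0("D|", rel, "(", head_w, ",", dep_w, ")")
  }
  out
}

# Lowercased mention surfaces per sentence: full surface, the underscore
# single-unit form, and each constituent token.
mention_token_sets <- function(mentions) {
  if (is.null(mentions) || nrow(mentions) == 0) {
    return(NULL)
  }
  sets <- list()
  for (i in seq_len(nrow(mentions))) {
    key <- as.character(mentions$sentence_index[i])
    txt <- tolower(mentions$text[i])
    toks <- strsplit(txt, "\\s+")[[1]]
    sets[[key]] <- unique(c(
      sets[[key]] %||% character(0),
      txt, gsub(" ", "_", txt, fixed = TRUE), toks
    ))
  }
  sets
}

#' Collapse gene mentions in a token stream to the anonymous tag
#'
#' Replaces each mention span with a single anonymous-tag token, so
#' multi-word gene names behave as one unit in n-gram extraction.
#'
#' @param sentences List of per-sentence token vectors.
#' @param mentions Mention tibble (`sentence_index`, `start`, `end`).
#' @param tag Replacement token.
#' @return The modified sentence list.
#' @export
anonymize_tokens <- function(sentences, mentions, tag = "PTNWORD") {
  if (is.null(mentions) || nrow(mentions) == 0) {
    return(sentences)
  }
  for (s in unique(mentions$sentence_index)) {
    rows <- mentions[mentions$sentence_index == s, , drop = FALSE]
    rows <- rows[order(-rows$start), , drop = FALSE] # replace right-to-left
    si <- s + 1
    if (si > length(sentences)) next
    toks <- sentences[[si]]
    for (i in seq_len(nrow(rows))) {
      a <- rows$start[i] + 1
      b <- rows$end[i]
      if (a < 1 || b > length(toks) || a > b) next
      toks <- c(
        if (a > 1) toks[1:(a - 1)], tag,
        if (b < length(toks)) toks[(b + 1):length(toks)]
      )
    }
    sentences[[si]] <- toks
  }
  sentences
}

#' All features of one document
#'
#' Runs the enabled feature families over a document and returns the feature
#' set (unique strings). Word n-grams see the anonymized token stream when
#' gene anonymization is on; substrings are computed from the raw tokens.
#'
#' @param title,abstract,mesh Document fields (`mesh`: character vector).
#' @param parses Parse tibble rows for this document, or `NULL`.
#' @param mentions Mention tibble rows for this document, or `NULL`.
#' @param config A [feature_config()].
#' @return Character vector: the document's feature set.
#' @export
document_features <- function(title, abstract = "", mesh = character(0),
                              parses = NULL, mentions = NULL,
                              config = feature_config()) {
  sentences <- tokenize_document(title, abstract)
  feats <- character(0)
  if (config$use_unigram || config$use_bigram || config$use_trigram) {
    ngram_sentences <- sentences
    if (config$anonymize_genes && !is.null(mentions) && nrow(mentions) > 0) {
      ngram_sentences <- anonymize_tokens(
        sentences, mentions, tolower(config$anonymous_tag)
      )
    }
    feats <- c(feats, word_ngram_features(ngram_sentences, config))
  }
  if (config$use_substrings) {
    feats <- c(feats, substring_features(unlist(sentences), config$substring_k))
  }
  if (config$use_mesh) {
    feats <- c(feats, mesh_features(mesh))
  }
  if (config$use_dependency) {
    feats <- c(feats, dependency_features(parses, mentions, config))
  }
  unique(feats)
}

#' Per-document feature sets for a corpus
#'
#' @param documents Corpus tibble (see [read_corpus()]).
#' @param parses Parse tibble for the whole corpus, or `NULL`.
#' @param mentions Mention tibble for the whole corpus, or `NULL`.
#' @param config A [feature_config()].
#' @return Named list (by `doc_id`) of feature-string sets.
#' @export
corpus_features <- function(documents, parses = NULL, mentions = NULL,
                            config = feature_config()) {
  parse_split <- if (!is.null(parses) && nrow(parses) > 0) {
    split(parses, parses$doc_id)
  } else {
    NULL
  }
  mention_split <- if (!is.null(mentions) && nrow(mentions) > 0) {
    split(mentions, mentions$doc_id)
  } else {
    NULL
  }
  out <- vector("list", nrow(documents))
  names(out) <- documents$doc_id
  for (i in seq_len(nrow(documents))) {
    id <- documents$doc_id[i]
    out[[i]] <- document_features(
      title = documents$title[i], abstract = documents$abstract[i],
      mesh = documents$mesh[[i]],
      parses = parse_split[[id]], mentions = mention_split[[id]],
      config = config
    )
  }
  out
}
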