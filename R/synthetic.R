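# Synthetic labeled corpus generator.
#
# Emulates the structure this classifier exploits in real PPI abstract
# triage: positives carry interaction trigger sentences between gene-like
# tokens, negatives use neutral verbs, MeSH descriptors are drawn
# label-conditionally, and every sentence is accompanied by a template
# dependency parse. All randomness is a pure function of `seed`.

ppi_trigger_phrases <- c(
  "interacts with", "binds", "phosphorylates", "activates",
  "forms a complex with", "associates with", "coimmunoprecipitates with"
)

ppi_neutral_verbs <- c(
  "describes", "measures", "surveys", "localizes near", "is expressed near",
  "was sequenced alongside", "is conserved relative to"
)

mesh_positive_pool <- c(
  "Protein Binding", "Protein Interaction Mapping", "Two-Hybrid System Techniques",
  "Signal Transduction", "Phosphorylation", "Protein Kinases"
)

mesh_negative_pool <- c(
  "Epidemiology", "Sequence Alignment", "Species Specificity",
  "Gene Expression Profiling", "Models, Statistical", "Cloning, Molecular"
)

mesh_shared_pool <- c("Humans", "Mice", "Animals", "Cell Line")

# Gene-like surface forms: mixed-case stem plus digit suffix, e.g. "Mtr3",
# "Krw12". Deterministic given the RNG state.
synthetic_gene_lexicon <- function(n) {
  cons <- strsplit("bcdfghjklmnpqrstvwz", "")[[1]]
  vow <- strsplit("aeiou", "")[[1]]
  stems <- vapply(seq_len(n), function(i) {
    paste0(
      toupper(sample(cons, 1)), sample(vow, 1), sample(cons, 1),
      if (stats::runif(1) < 0.4) paste0(sample(vow, 1), sample(cons, 1)) else ""
    )
  }, character(1))
  paste0(stems, sample(1:99, n, replace = TRUE))
}

synthetic_background_vocab <- function(n) {
  cons <- strsplit("bcdfghjklmnprstvw", "")[[1]]
  vow <- strsplit("aeiou", "")[[1]]
  vapply(seq_len(n), function(i) {
    k <- sample(2:4, 1)
    paste0(vapply(seq_len(k), function(j) {
      paste0(sample(cons, 1), sample(vow, 1))
    }, character(1)), collapse = "")
  }, character(1))
}

#' Generate a synthetic labeled PPI corpus with parses and gold mentions
#'
#' Builds `n_docs` abstract records. The first `ceiling(pos_fraction *
#' n_docs)` documents (by index) are positive, so class counts are exact
#' rather than sampled. Every positive document contains at least one
#' trigger sentence `<GENE> <trigger> <GENE>` (triggers drawn from
#' `trigger_phrases`); negative documents use neutral verbs between the same
#' kinds of tokens. Gene-like tokens come from a synthetic lexicon of
#' mixed-case stems with digit suffixes. Background tokens are
#' label-independent noise; MeSH descriptors are drawn label-conditionally
#' with a shared pool. Each sentence also yields a template dependency parse:
#' `(subj, verb, gene1)` and `(obj, verb, gene2)`, plus `(nmod, noun,
#' background)` relations for filler sentences.
#'
#' @param n_docs Number of documents.
#' @param pos_fraction Fraction of positive documents, in `[0, 1]`.
#' @param vocab_size Background vocabulary size.
#' @param n_trigger_phrases How many distinct trigger phrases to use (at most
#'   the built-in list length).
#' @param gene_token_rate Expected number of additional gene tokens planted
#'   in filler sentences (per sentence).
#' @param noise_rate Expected number of label-independent background tokens
#'   appended per sentence.
#' @param n_genes Size of the synthetic gene lexicon.
#' @param sentences_per_doc Abstract length range (filler sentences),
#'   length-2 integer vector.
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @return A list of class `ppi_synthetic_corpus` with elements `documents`
#'   (corpus tibble as from [read_corpus()]), `labels` (tibble `doc_id`,
#'   `label`), `parses` (tibble as from [read_parses()]), `mentions` (gold
#'   gene-mention tibble: `doc_id`, `sentence_index`, `start`, `end`, `text`;
#'   spans are 0-based half-open token units), and `gene_lexicon`
#'   (character).
#' @examples
#' syn <- synthetic_corpus(n_docs = 10, pos_fraction = 0.5, seed = 1)
#' syn$labels
#' @export
synthetic_corpus <- function(n_docs = 400, pos_fraction = 0.5,
                             vocab_size = 200, n_trigger_phrases = 5,
                             gene_token_rate = 1, noise_rate = 3,
                             n_genes = 60, sentences_per_doc = c(2L, 4L),
                             seed = 1) {
  if (pos_fraction < 0 || pos_fraction > 1) {
    abort("pos_fraction must be in [0, 1]")
  }
  stopifnot(n_docs >= 1, vocab_size >= 1, n_trigger_phrases >= 1)
  n_pos <- as.integer(ceiling(pos_fraction * n_docs))
  triggers <- head(ppi_trigger_phrases, n_trigger_phrases)

  with_seed(seed, {
    lexicon <- unique(synthetic_gene_lexicon(n_genes))
    vocab <- unique(synthetic_background_vocab(vocab_size))

    docs <- vector("list", n_docs)
    parses <- vector("list", n_docs)
    mentions <- vector("list", n_docs)
    for (d in seq_len(n_docs)) {
      positive <- d <= n_pos
      built <- build_synthetic_document(
        doc_id = sprintf("syn%04d", d), positive = positive,
        triggers = triggers, lexicon = lexicon, vocab = vocab,
        gene_token_rate = gene_token_rate, noise_rate = noise_rate,
        sentences_per_doc = sentences_per_doc
      )
      docs[[d]] <- built$document
      parses[[d]] <- built$parses
      mentions[[d]] <- built$mentions
    }
    structure(
      list(
        documents = dplyr::bind_rows(docs),
        labels = tibble(
          doc_id = sprintf("syn%04d", seq_len(n_docs)),
          label = ifelse(seq_len(n_docs) <= n_pos, 1L, -1L)
        ),
        parses = dplyr::bind_rows(parses),
        mentions = dplyr::bind_rows(mentions),
        gene_lexicon = lexicon
      ),
      class = "ppi_synthetic_corpus"
    )
  })
}

# One synthetic document: a title sentence plus filler sentences; positives
# get >= 1 trigger sentence. Returns the document row, its template parse
# rows and the gold mention rows.
build_synthetic_document <- function(doc_id, positive, triggers, lexicon,
                                     vocab, gene_token_rate, noise_rate,
                                     sentences_per_doc) {
  n_fill <- sample(seq(sentences_per_doc[1], sentences_per_doc[2]), 1)
  sentences <- list()
  parse_rows <- list()
  mention_rows <- list()
  sent_idx <- 0L

  add_sentence <- function(tokens, rels, ments) {
    sentences[[length(sentences) + 1]] <<- tokens
    if (nrow(rels) > 0) {
      rels$doc_id <- doc_id
      rels$sentence_index <- sent_idx
      parse_rows[[length(parse_rows) + 1]] <<-
        rels[, c("doc_id", "sentence_index", "relation", "head", "dependent")]
    }
    if (nrow(ments) > 0) {
      ments$doc_id <- doc_id
      ments$sentence_index <- sent_idx
      mention_rows[[length(mention_rows) + 1]] <<-
        ments[, c("doc_id", "sentence_index", "start", "end", "text")]
    }
    sent_idx <<- sent_idx + 1L
  }

  # core sentence: gene1 <verb phrase> gene2, with noise appended
  core_sentence <- function(verb_phrase) {
    g <- sample(lexicon, 2, replace = FALSE)
    verb_tokens <- strsplit(verb_phrase, " ", fixed = TRUE)[[1]]
    noise <- sample_noise(vocab, noise_rate)
    tokens <- c(g[1], verb_tokens, g[2], noise)
    nv <- length(verb_tokens)
    rels <- data.frame(
      relation = c("subj", "obj"),
      head = c(verb_tokens[1], verb_tokens[1]),
      dependent = c(g[1], g[2])
    )
    ments <- data.frame(
      start = c(0L, 1L + nv), end = c(1L, 2L + nv), text = g
    )
    if (length(noise) > 0) {
      rels <- rbind(rels, data.frame(
        relation = "nmod", head = verb_tokens[1], dependent = noise[1]
      ))
    }
    add_sentence(tokens, rels, ments)
  }

  filler_sentence <- function() {
    subj <- sample(vocab, 1)
    verb <- sample(c("concerns", "reports", "examines"), 1)
    noise <- sample_noise(vocab, max(noise_rate, 1))
    tokens <- c("this", "study", verb, subj, noise)
    rels <- data.frame(relation = "dobj", head = verb, dependent = subj)
    ments <- data.frame(start = integer(0), end = integer(0), text = character(0))
    # optionally plant extra gene tokens (gold-annotated, no trigger)
    n_extra <- stats::rpois(1, gene_token_rate)
    if (n_extra > 0) {
      extra <- sample(lexicon, min(n_extra, 3), replace = FALSE)
      start0 <- length(tokens)
      tokens <- c(tokens, extra)
      ments <- data.frame(
        start = start0 + seq_along(extra) - 1L,
        end = start0 + seq_along(extra),
        text = extra
      )
    }
    add_sentence(tokens, rels, ments)
  }

  if (positive) {
    core_sentence(sample(triggers, 1)) # title guarantees >= 1 trigger
  } else {
    core_sentence(sample(ppi_neutral_verbs, 1))
  }
  for (i in seq_len(n_fill)) {
    if (positive && stats::runif(1) < 0.5) {
      core_sentence(sample(triggers, 1))
    } else if (!positive && stats::runif(1) < 0.5) {
      core_sentence(sample(ppi_neutral_verbs, 1))
    } else {
      filler_sentence()
    }
  }

  pool <- if (positive) mesh_positive_pool else mesh_negative_pool
  mesh <- c(
    sample(pool, sample(1:3, 1)),
    sample(mesh_shared_pool, sample(0:2, 1))
  )

  render <- function(tokens) {
    paste0(paste(tokens, collapse = " "), ".")
  }
  title <- render(sentences[[1]])
  abstract <- if (length(sentences) > 1) {
    paste(vapply(sentences[-1], function(s) {
      s[1] <- capitalize_token(s[1])
      render(s)
    }, character(1)), collapse = " ")
  } else {
    ""
  }

  list(
    document = tibble(
      doc_id = doc_id, title = title, abstract = abstract, mesh = list(mesh)
    ),
    parses = if (length(parse_rows)) dplyr::bind_rows(parse_rows) else empty_parses(),
    mentions = if (length(mention_rows)) {
      dplyr::bind_rows(mention_rows)
    } else {
      tibble(
        doc_id = character(), sentence_index = integer(),
        start = integer(), end = integer(), text = character()
      )
    }
  )
}

sample_noise <- function(vocab, rate) {
  n <- stats::rpois(1, rate)
  if (n == 0) character(0) else sample(vocab, min(n, length(vocab)), replace = TRUE)
}

capitalize_token <- function(x) {
  paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
}

#' @export
print.ppi_synthetic_corpus <- function(x, ...) {
  cat(
    "Synthetic PPI corpus:", nrow(x$documents), "documents (",
    sum(x$labels$label == 1L), "positive /", sum(x$labels$label == -1L),
    "negative ),", nrow(x$parses), "dependency relations,",
    nrow(x$mentions), "gold gene mentions\n"
  )
  invisible(x)
}
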