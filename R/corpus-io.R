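# Readers and writers for the external formats: Medline tagged records or a
# 4-column TSV corpus, two-column label tables, dependency parses (flat TSV or
# CoNLL-X token tables), and SVMlight-style sparse binary vectors.

#' Read a corpus of abstract records
#'
#' Accepts either the Medline tagged format (a concatenation of records with
#' `PMID-`, `TI  -`, `AB  -` and `MH  -` fields, continuation lines indented)
#' or a tab-separated dialect with columns `doc_id`, `title`, `abstract`,
#' `mesh` (semicolon-joined descriptors). Only these four fields are
#' consumed: titles and abstracts feed word and syntactic features, MeSH
#' descriptors feed MeSH features.
#'
#' @param x Path to a file, or the file contents as a single string /
#'   character vector of lines.
#' @return A tibble with columns `doc_id` (character), `title`, `abstract`
#'   (character, empty string when the record has none) and `mesh`
#'   (list-column of character vectors).
#' @examples
#' read_corpus("PMID- 1\nTI  - A binds B.\nMH  - Protein Binding")
#' @export
read_corpus <- function(x) {
  lines <- read_input_lines(x)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    return(empty_corpus())
  }
  if (any(grepl("^PMID-", lines))) {
    read_medline_tagged(lines)
  } else {
    read_corpus_tsv(lines)
  }
}

empty_corpus <- function() {
  tibble(
    doc_id = character(), title = character(), abstract = character(),
    mesh = list()
  )
}

read_medline_tagged <- function(lines) {
  # every PMID line opens a new record; blank lines are ignored
  rec_id <- cumsum(grepl("^PMID-", lines))
  keep <- nzchar(trimws(lines)) & rec_id > 0
  groups <- split(lines[keep], rec_id[keep])
  docs <- purrr::imap(groups, function(rec, ordinal) {
    parse_medline_record(rec, as.integer(ordinal))
  })
  out <- dplyr::bind_rows(docs)
  dup <- out$doc_id[duplicated(out$doc_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate doc_id in corpus: ", paste(unique(dup), collapse = ", ")))
  }
  out
}

parse_medline_record <- function(rec, ordinal) {
  # fold continuation lines (leading whitespace) into the preceding field
  tag <- sub("^([A-Z]+) *-.*$", "\\1", rec)
  is_cont <- grepl("^\\s", rec) | !grepl("^[A-Z]+ *- ?", rec)
  tag[is_cont] <- NA
  tag <- vctrs_fill_down(tag)
  value <- ifelse(is_cont, trimws(rec), sub("^[A-Z]+ *- ?", "", rec))
  fields <- split(value, factor(tag, levels = unique(tag)))
  fields <- lapply(fields, paste, collapse = " ")
  mh <- value[tag == "MH" & !is.na(tag)]
  # MH entries are one descriptor per MH line (continuations already folded)
  mh_cont <- is_cont[tag == "MH" & !is.na(tag)]
  mesh <- character(0)
  for (i in seq_along(mh)) {
    if (i > 1 && mh_cont[i]) {
      mesh[length(mesh)] <- paste(mesh[length(mesh)], mh[i])
    } else {
      mesh <- c(mesh, mh[i])
    }
  }
  if (is.null(fields$PMID) || !nzchar(trimws(fields$PMID))) {
    abort(paste0("record ", ordinal, " has no PMID"))
  }
  tibble(
    doc_id = trimws(fields$PMID),
    title = trimws(fields$TI %||% ""),
    abstract = trimws(fields$AB %||% ""),
    mesh = list(trimws(mesh))
  )
}

vctrs_fill_down <- function(x) {
  for (i in seq_along(x)) {
    if (is.na(x[i]) && i > 1) x[i] <- x[i - 1]
  }
  x
}

read_corpus_tsv <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  docs <- purrr::imap(parts, function(p, ordinal) {
    if (length(p) < 1 || !nzchar(trimws(p[1]))) {
      abort(paste0("record ", ordinal, " has no doc_id"))
    }
    mesh <- if (length(p) >= 4 && nzchar(p[4])) {
      trimws(strsplit(p[4], ";", fixed = TRUE)[[1]])
    } else {
      character(0)
    }
    tibble(
      doc_id = p[1],
      title = if (length(p) >= 2) p[2] else "",
      abstract = if (length(p) >= 3) p[3] else "",
      mesh = list(mesh)
    )
  })
  out <- dplyr::bind_rows(docs)
  dup <- out$doc_id[duplicated(out$doc_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate doc_id in corpus: ", paste(unique(dup), collapse = ", ")))
  }
  out
}

#' Write a corpus as Medline tagged records
#'
#' Inverse of [read_corpus()] for the tagged dialect: each document becomes a
#' `PMID-`/`TI  -`/`AB  -`/`MH  -` record, records separated by blank lines.
#'
#' @param documents Corpus tibble (see [read_corpus()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(documents, path) {
  recs <- purrr::pmap_chr(
    documents,
    function(doc_id, title, abstract, mesh, ...) {
      lines <- c(
        paste0("PMID- ", doc_id),
        paste0("TI  - ", title),
        if (nzchar(abstract)) paste0("AB  - ", abstract),
        if (length(mesh) > 0) paste0("MH  - ", mesh)
      )
      paste(lines, collapse = "\n")
    }
  )
  writeLines(paste(recs, collapse = "\n\n"), path)
  invisible(path)
}

#' Read document labels
#'
#' Two-column tab-separated `doc_id<TAB>label`. Accepted label spellings:
#' `1`/`-1`, `+1`, `true`/`false`, `P`/`N` (case-insensitive). `+1` marks a
#' PPI-relevant document.
#'
#' @inheritParams read_corpus
#' @return A tibble with columns `doc_id` (character) and `label` (integer,
#'   +1 or -1).
#' @export
read_labels <- function(x) {
  lines <- read_input_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(doc_id = character(), label = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2)
  if (length(bad) > 0) {
    abort(paste0("label line ", bad[1], " does not have two columns"))
  }
  ids <- vapply(parts, `[[`, character(1), 1)
  raw <- trimws(vapply(parts, `[[`, character(1), 2))
  lab <- parse_label_token(raw)
  out <- tibble(doc_id = ids, label = lab)
  chk <- dplyr::distinct(out)
  if (anyDuplicated(chk$doc_id) > 0) {
    dup <- chk$doc_id[duplicated(chk$doc_id)]
    abort(paste0("conflicting labels for doc_id: ", paste(unique(dup), collapse = ", ")))
  }
  dplyr::distinct(out)
}

parse_label_token <- function(raw) {
  key <- tolower(raw)
  map <- c(
    "1" = 1L, "+1" = 1L, "-1" = -1L, "true" = 1L, "false" = -1L,
    "p" = 1L, "n" = -1L
  )
  lab <- unname(map[key])
  if (anyNA(lab)) {
    abort(paste0("unknown label token: '", raw[which(is.na(lab))[1]], "'"))
  }
  lab
}

#' Write document labels
#'
#' @param labels Tibble with `doc_id`, `label` columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  assert_labels(labels)
  writeLines(paste(labels$doc_id, labels$label, sep = "\t"), path)
  invisible(path)
}

#' Read dependency parses
#'
#' Two dialects are accepted:
#' \itemize{
#'   \item flat TSV, one relation per line:
#'     `doc_id<TAB>sentence_index<TAB>relation<TAB>head<TAB>dependent`;
#'   \item CoNLL-X token tables (10 columns, sentences separated by blank
#'     lines) preceded by a `#doc <id>` comment naming the document; the
#'     (DEPREL, head FORM, dependent FORM) triple of each non-root token is
#'     converted. Root links produce no relation; a token whose HEAD index
#'     does not exist is skipped with a warning.
#' }
#'
#' @inheritParams read_corpus
#' @return A tibble with columns `doc_id`, `sentence_index` (0-based
#'   integer), `relation`, `head`, `dependent`, in input order.
#' @export
read_parses <- function(x) {
  lines <- read_input_lines(x)
  content <- lines[nzchar(trimws(lines))]
  if (length(content) == 0) {
    return(empty_parses())
  }
  first_cols <- strsplit(content[1], "\t", fixed = TRUE)[[1]]
  if (grepl("^#doc\\b", content[1]) || length(first_cols) >= 8) {
    read_parses_conllx(lines)
  } else {
    read_parses_tsv(content)
  }
}

empty_parses <- function() {
  tibble(
    doc_id = character(), sentence_index = integer(),
    relation = character(), head = character(), dependent = character()
  )
}

read_parses_tsv <- function(lines) {
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 5)
  if (length(bad) > 0) {
    abort(paste0("parse line ", bad[1], " does not have five columns"))
  }
  tibble(
    doc_id = vapply(parts, `[[`, character(1), 1),
    sentence_index = as.integer(vapply(parts, `[[`, character(1), 2)),
    relation = vapply(parts, `[[`, character(1), 3),
    head = vapply(parts, `[[`, character(1), 4),
    dependent = vapply(parts, `[[`, character(1), 5)
  )
}

read_parses_conllx <- function(lines) {
  doc <- NA_character_
  sent <- -1L
  tok_form <- character(0)
  tok_head <- integer(0)
  tok_rel <- character(0)
  out <- list()

  flush_sentence <- function() {
    if (length(tok_form) == 0) {
      return()
    }
    for (i in seq_along(tok_form)) {
      h <- tok_head[i]
      if (is.na(h) || h == 0) next # root link: no relation feature
      if (h < 1 || h > length(tok_form)) {
        warn(paste0(
          "doc ", doc, " sentence ", sent, ": token ", i,
          " has dangling head index ", h, "; skipped"
        ))
        next
      }
      out[[length(out) + 1]] <<- tibble(
        doc_id = doc, sentence_index = sent,
        relation = tok_rel[i], head = tok_form[h], dependent = tok_form[i]
      )
    }
  }

  for (line in lines) {
    if (grepl("^#doc\\b", line)) {
      flush_sentence()
      tok_form <- character(0); tok_head <- integer(0); tok_rel <- character(0)
      doc <- trimws(sub("^#doc\\s*", "", line))
      sent <- -1L
      next
    }
    if (!nzchar(trimws(line))) {
      flush_sentence()
      tok_form <- character(0); tok_head <- integer(0); tok_rel <- character(0)
      next
    }
    cols <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(tok_form) == 0) sent <- sent + 1L
    tok_form <- c(tok_form, cols[2])
    tok_head <- c(tok_head, suppressWarnings(as.integer(cols[7])))
    tok_rel <- c(tok_rel, cols[8])
  }
  flush_sentence()
  if (length(out) == 0) {
    return(empty_parses())
  }
  dplyr::bind_rows(out)
}

#' Write dependency parses in the flat TSV dialect
#'
#' @param parses Parse tibble (see [read_parses()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parses <- function(parses, path) {
  writeLines(
    paste(parses$doc_id, parses$sentence_index, parses$relation,
      parses$head, parses$dependent,
      sep = "\t"
    ),
    path
  )
  invisible(path)
}

#' Write sparse binary feature vectors (SVMlight dialect)
#'
#' One line per document: `<label> <idx>:1 <idx>:1 ...` with strictly
#' increasing 1-based indices. The feature vocabulary goes to a sidecar file
#' via [write_vocabulary()].
#'
#' @param vectors List of sorted integer index vectors (one per document).
#' @param labels Integer vector of +1/-1, same length as `vectors`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sparse_vectors <- function(vectors, labels, path) {
  stopifnot(length(vectors) == length(labels), all(labels %in% c(-1L, 1L)))
  lines <- purrr::map2_chr(vectors, labels, function(idx, y) {
    lab <- if (y > 0) "+1" else "-1"
    if (length(idx) == 0) {
      lab
    } else {
      paste(lab, paste0(sort(idx), ":1", collapse = " "))
    }
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read sparse binary feature vectors (SVMlight dialect)
#'
#' @inheritParams read_corpus
#' @return A list with `vectors` (list of increasing integer index vectors)
#'   and `labels` (integer +1/-1).
#' @export
read_sparse_vectors <- function(x) {
  lines <- read_input_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  labels <- integer(length(lines))
  vectors <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    labels[i] <- parse_label_token(parts[1])
    if (length(parts) > 1) {
      idx <- as.integer(sub(":.*$", "", parts[-1]))
      if (any(diff(idx) <= 0) || any(idx < 1)) {
        abort(paste0("line ", i, ": indices must be strictly increasing and >= 1"))
      }
      vectors[[i]] <- idx
    } else {
      vectors[[i]] <- integer(0)
    }
  }
  list(vectors = vectors, labels = labels)
}
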