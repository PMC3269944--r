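#' Tokenize text into sentences of lowercased word tokens
#'
#' Splits text into sentences at `.`, `?` or `!` followed by a space and an
#' uppercase letter, then into word tokens. Tokens are lowercased; punctuation
#' is dropped except hyphens internal to a token, so mentions such as
#' `"MEK-1"` and `"p53"` survive as single tokens.
#'
#' @param text Character scalar (or vector, concatenated with sentence breaks).
#' @return A list with one character vector of tokens per sentence. Empty
#'   sentences are dropped; empty input yields an empty list.
#' @examples
#' tokenize_sentences("MEK-1 binds p53. It is phosphorylated.")
#' @export
tokenize_sentences <- function(text) {
  text <- paste(text[nzchar(text)], collapse = " . ")
  if (!nzchar(trimws(text))) {
    return(list())
  }
  sents <- strsplit(text, "(?<=[.?!])\\s+(?=[A-Z])", perl = TRUE)[[1]]
  out <- lapply(sents, function(s) {
    toks <- regmatches(s, gregexpr("[[:alnum:]]+(?:-[[:alnum:]]+)*", s))[[1]]
    tolower(toks)
  })
  out[lengths(out) > 0]
}

#' Flat token sequence for a document
#'
#' Title and abstract are concatenated with a sentence boundary between them,
#' so n-grams never bridge the two fields.
#'
#' @param title,abstract Character scalars.
#' @return A list of per-sentence token vectors (see [tokenize_sentences()]).
#' @export
tokenize_document <- function(title, abstract = "") {
  parts <- c(title, abstract)
  parts <- parts[!is.na(parts) & nzchar(trimws(parts))]
  if (length(parts) == 0) {
    return(list())
  }
  c(tokenize_sentences(parts[1]),
    if (length(parts) > 1) tokenize_sentences(parts[2]) else list())
}
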