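# Priority Model for gene/protein name detection.
#
# Each token t carries two probabilities: p, the probability that t indicates
# the gene class, and q, the probability that t is a more reliable indicator
# than any token to its left. A name t1...tk is scored as a mixture of the
# tokens' p values in which tokens further right dominate: the weight of
# token i is q'_i * prod_{j>i} (1 - q_j), with q' of the leftmost token fixed
# to 1 so the weights always sum to one.

PRIORITY_EPS <- 1e-6

#' Score a token sequence under a Priority Model
#'
#' Returns the model probability that the name belongs to the gene class:
#' a right-priority convex combination of the per-token class probabilities
#' `p`, weighted by the reliability probabilities `q` (see
#' [priority_model()]). The score always lies between the smallest and
#' largest `p` of the constituent tokens.
#'
#' @param model A `priority_model` object.
#' @param tokens Non-empty character vector, tokens ordered left to right.
#' @return A probability in `[0, 1]`.
#' @examples
#' m <- priority_model(c("insulin receptor", "p53"), c("heavy table", "blue chair"))
#' score_name(m, c("insulin", "receptor"))
#' @export
score_name <- function(model, tokens) {
  stopifnot(inherits(model, "priority_model"))
  if (length(tokens) == 0) {
    abort("cannot score an empty token sequence")
  }
  p <- lookup_stat(model, tokens, "p")
  q <- lookup_stat(model, tokens, "q")
  sum(priority_weights(q) * p)
}

# lambda_i = q'_i * prod_{j>i}(1-q_j), q'_1 = 1; sums to 1 by telescoping.
priority_weights <- function(q) {
  k <- length(q)
  qp <- q
  qp[1] <- 1
  cp <- rev(cumprod(rev(c((1 - q)[-1], 1)))) # cp[i] = prod_{j>i}(1-q_j)
  qp * cp
}

lookup_stat <- function(model, tokens, which) {
  idx <- match(tokens, model$stats$token)
  vals <- model$stats[[which]][idx]
  default <- if (which == "p") model$default_p else model$default_q
  vals[is.na(vals)] <- default
  vals
}

#' Fit a Priority Model from positive and negative name lists
#'
#' Maximizes the Bernoulli log-likelihood of the class labels under the
#' right-priority score of [score_name()]. Both `p` and `q` are optimized in
#' logit parameterization (initialized at logit 0, i.e. 0.5) with the BFGS
#' quasi-Newton method and analytic gradients, so the fit is deterministic.
#' Fitted probabilities are clipped to `[1e-6, 1 - 1e-6]` to keep
#' single-class tokens finite.
#'
#' @param positive_names,negative_names Names of the gene class and of the
#'   background class: either a character vector (tokens space-separated
#'   within each name) or a list of token vectors. Both must be non-empty.
#' @param default_p,default_q Probabilities used for tokens unseen in
#'   training (default 0.5: uninformative).
#' @param decision_threshold Score cutoff used by [tag_mentions()].
#' @param max_iterations BFGS iteration cap.
#' @return An object of class `priority_model`: a list with `stats` (tibble
#'   `token`, `p`, `q`), the defaults, the threshold, and `convergence`
#'   metadata.
#' @export
priority_model <- function(positive_names, negative_names,
                           default_p = 0.5, default_q = 0.5,
                           decision_threshold = 0.5,
                           max_iterations = 200) {
  pos <- as_token_list(positive_names)
  neg <- as_token_list(negative_names)
  if (length(pos) == 0 || length(neg) == 0) {
    abort("both name lists must be non-empty")
  }
  names_tok <- c(pos, neg)
  y <- c(rep(1, length(pos)), rep(0, length(neg)))
  vocab <- sort(unique(unlist(names_tok)))
  V <- length(vocab)
  name_idx <- lapply(names_tok, match, table = vocab)

  nll <- function(par) {
    p <- stats::plogis(par[1:V])
    q <- stats::plogis(par[(V + 1):(2 * V)])
    s <- vapply(name_idx, function(idx) {
      sum(priority_weights(q[idx]) * p[idx])
    }, numeric(1))
    s <- pmin(pmax(s, PRIORITY_EPS), 1 - PRIORITY_EPS)
    -sum(y * log(s) + (1 - y) * log(1 - s))
  }

  grad <- function(par) {
    p <- stats::plogis(par[1:V])
    q <- stats::plogis(par[(V + 1):(2 * V)])
    gp <- numeric(V)
    gq <- numeric(V)
    for (n in seq_along(name_idx)) {
      idx <- name_idx[[n]]
      k <- length(idx)
      lam <- priority_weights(q[idx])
      pn <- p[idx]
      s <- sum(lam * pn)
      s <- min(max(s, PRIORITY_EPS), 1 - PRIORITY_EPS)
      ds <- (s - y[n]) / (s * (1 - s)) # d(-loglik)/ds
      # d s / d p_i = lambda_i
      for (i in seq_len(k)) {
        gp[idx[i]] <- gp[idx[i]] + ds * lam[i]
      }
      # d s / d q_i: direct term through lambda_i (i >= 2) and the
      # (1 - q_i) factors inside every lambda_j with j < i
      if (k >= 2) {
        cum_lp <- cumsum(lam * pn) # sum_{j<=i} lambda_j p_j
        for (i in 2:k) {
          qi <- q[idx[i]]
          direct <- if (qi > 0) lam[i] / qi * pn[i] else 0
          left <- cum_lp[i - 1] / (1 - qi)
          gq[idx[i]] <- gq[idx[i]] + ds * (direct - left)
        }
      }
    }
    c(gp * p * (1 - p), gq * q * (1 - q))
  }

  fit <- stats::optim(
    par = rep(0, 2 * V), fn = nll, gr = grad, method = "BFGS",
    control = list(maxit = max_iterations, reltol = 1e-10)
  )
  p_hat <- pmin(pmax(stats::plogis(fit$par[1:V]), PRIORITY_EPS), 1 - PRIORITY_EPS)
  q_hat <- pmin(pmax(stats::plogis(fit$par[(V + 1):(2 * V)]), PRIORITY_EPS), 1 - PRIORITY_EPS)

  structure(
    list(
      stats = tibble(token = vocab, p = p_hat, q = q_hat),
      default_p = default_p, default_q = default_q,
      decision_threshold = decision_threshold,
      convergence = list(
        value = fit$value, counts = fit$counts, converged = fit$convergence == 0
      )
    ),
    class = "priority_model"
  )
}

as_token_list <- function(x) {
  if (is.list(x)) {
    lapply(x, as.character)
  } else {
    strsplit(tolower(as.character(x)), "\\s+")
  }
}

#' @export
print.priority_model <- function(x, ...) {
  cat(
    "Priority Model:", nrow(x$stats), "tokens; decision threshold",
    x$decision_threshold, "\n"
  )
  invisible(x)
}

#' @rdname tidy_ppitriage
#' @method tidy priority_model
#' @export
tidy.priority_model <- function(x, ...) {
  x$stats
}

#' Tag gene mentions in tokenized sentences
#'
#' Scores each candidate phrase with [score_name()]. A candidate becomes a
#' mention iff its score exceeds the model's decision threshold and its
#' surface string is not purely numeric (an all-digit string is never a gene
#' name). Overlapping accepted candidates within a sentence are resolved
#' leftmost-longest. Multi-word mentions are single units downstream
#' (anonymization, parsing).
#'
#' @param model A `priority_model`.
#' @param sentences List of per-sentence token vectors (e.g. from
#'   [tokenize_document()]).
#' @param candidates Tibble with columns `sentence_index` (0-based), `start`,
#'   `end` (0-based half-open token spans), e.g. from
#'   [candidate_phrases()]. Tests and callers may supply spans directly.
#' @param doc_id Identifier copied onto the output rows.
#' @return A tibble of mentions: `doc_id`, `sentence_index`, `start`, `end`,
#'   `text`, `score`, non-overlapping within each sentence.
#' @export
tag_mentions <- function(model, sentences, candidates, doc_id = NA_character_) {
  empty <- tibble(
    doc_id = character(), sentence_index = integer(),
    start = integer(), end = integer(), text = character(), score = numeric()
  )
  if (is.null(candidates) || nrow(candidates) == 0) {
    return(empty)
  }
  scored <- purrr::pmap(candidates, function(sentence_index, start, end, ...) {
    toks <- sentences[[sentence_index + 1]][(start + 1):end]
    surface <- paste(toks, collapse = " ")
    sc <- score_name(model, tolower(toks))
    all_numeric <- grepl("^[0-9]+$", gsub("[ -]", "", surface))
    list(
      sentence_index = sentence_index, start = start, end = end,
      text = surface, score = sc,
      accepted = !all_numeric && sc > model$decision_threshold
    )
  })
  scored <- dplyr::bind_rows(lapply(scored, as_tibble))
  scored <- scored[scored$accepted, , drop = FALSE]
  if (nrow(scored) == 0) {
    return(empty)
  }
  # leftmost-longest within each sentence
  scored <- scored[order(scored$sentence_index, scored$start, -scored$end), ]
  kept <- list()
  last_end <- list()
  for (i in seq_len(nrow(scored))) {
    s <- as.character(scored$sentence_index[i])
    prev <- last_end[[s]] %||% -1L
    if (scored$start[i] >= prev) {
      kept[[length(kept) + 1]] <- scored[i, ]
      last_end[[s]] <- scored$end[i]
    }
  }
  out <- dplyr::bind_rows(kept)
  tibble(
    doc_id = doc_id,
    sentence_index = as.integer(out$sentence_index),
    start = as.integer(out$start), end = as.integer(out$end),
    text = out$text, score = out$score
  )
}

#' Regex fallback candidate chunker
#'
#' A stand-in for a noun-phrase chunker when none is plugged in: proposes
#' maximal runs of tokens that look name-like (capitalized, or containing a
#' digit) from the raw (case-preserved) token stream.
#'
#' @param title,abstract Document text fields.
#' @return A tibble of candidate spans (`sentence_index`, `start`, `end`)
#'   alongside the raw `sentences` token list, as a list with elements
#'   `candidates` and `sentences`.
#' @export
candidate_phrases <- function(title, abstract = "") {
  raw <- tokenize_document_raw(title, abstract)
  rows <- list()
  for (s in seq_along(raw)) {
    toks <- raw[[s]]
    namelike <- grepl("^[A-Z]", toks) | grepl("[0-9]", toks)
    # first token of a sentence is capitalized by orthography; require more
    namelike[1] <- namelike[1] && grepl("[0-9]|[A-Z].*[A-Z0-9]", toks[1])
    r <- rle(namelike)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in seq_along(r$values)) {
      if (r$values[j]) {
        rows[[length(rows) + 1]] <- tibble(
          sentence_index = s - 1L,
          start = starts[j] - 1L, end = ends[j]
        )
      }
    }
  }
  list(
    candidates = if (length(rows)) {
      dplyr::bind_rows(rows)
    } else {
      tibble(sentence_index = integer(), start = integer(), end = integer())
    },
    sentences = raw
  )
}

# Case-preserving tokenization with the same token/sentence rules as
# tokenize_document().
tokenize_document_raw <- function(title, abstract = "") {
  parts <- c(title, abstract)
  parts <- parts[!is.na(parts) & nzchar(trimws(parts))]
  if (length(parts) == 0) {
    return(list())
  }
  one <- function(text) {
    sents <- strsplit(text, "(?<=[.?!])\\s+(?=[A-Z])", perl = TRUE)[[1]]
    out <- lapply(sents, function(s) {
      regmatches(s, gregexpr("[[:alnum:]]+(?:-[[:alnum:]]+)*", s))[[1]]
    })
    out[lengths(out) > 0]
  }
  c(one(parts[1]), if (length(parts) > 1) one(parts[2]) else list())
}

#' Serialize / deserialize a Priority Model
#'
#' TSV body `(token, p, q)` preceded by a one-line header carrying the
#' defaults and decision threshold.
#'
#' @param model A `priority_model`.
#' @param path File path.
#' @return `write_priority_model()` returns `path` invisibly;
#'   `read_priority_model()` returns the model.
#' @export
write_priority_model <- function(model, path) {
  header <- sprintf(
    "#priority_model\tdefault_p=%.17g\tdefault_q=%.17g\tthreshold=%.17g",
    model$default_p, model$default_q, model$decision_threshold
  )
  body <- sprintf("%s\t%.17g\t%.17g", model$stats$token, model$stats$p, model$stats$q)
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_priority_model
#' @export
read_priority_model <- function(path) {
  lines <- read_input_lines(path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  getval <- function(key) {
    as.numeric(sub(paste0(key, "="), "", hdr[startsWith(hdr, paste0(key, "="))]))
  }
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  structure(
    list(
      stats = tibble(
        token = vapply(body, `[[`, character(1), 1),
        p = as.numeric(vapply(body, `[[`, character(1), 2)),
        q = as.numeric(vapply(body, `[[`, character(1), 3))
      ),
      default_p = getval("default_p"),
      default_q = getval("default_q"),
      decision_threshold = getval("threshold"),
      convergence = NULL
    ),
    class = "priority_model"
  )
}
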