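# Priority Model: scoring algebra, training, and mention tagging.

make_manual_model <- function(tokens, p, q, threshold = 0.5) {
  structure(
    list(
      stats = tibble::tibble(token = tokens, p = p, q = q),
      default_p = 0.5, default_q = 0.5, decision_threshold = threshold,
      convergence = NULL
    ),
    class = "priority_model"
  )
}

test_that("score_name closed forms: single token, equal p, two-token expansion", {
  m <- make_manual_model(c("a", "b"), p = c(0.9, 0.2), q = c(0.1, 0.8))
  # k = 1 reduces to p regardless of q
  expect_equal(score_name(m, "a"), 0.9)
  # two tokens (p1=0.2 q1 arbitrary; p2=0.9 q2=0.7): 0.7*0.9 + 0.3*0.2
  m2 <- make_manual_model(c("x", "y"), p = c(0.2, 0.9), q = c(0.33, 0.7))
  expect_equal(score_name(m2, c("x", "y")), 0.69)
  # all tokens sharing p = c gives c for any q
  m3 <- make_manual_model(c("u", "v", "w"), p = rep(0.37, 3), q = c(0.9, 0.1, 0.5))
  expect_equal(score_name(m3, c("u", "v", "w")), 0.37)
  expect_error(score_name(m, character(0)), "empty")
})

test_that("score_name equals the recursive right-priority oracle (length <= 4)", {
  alphabet <- c("t1", "t2", "t3")
  withr::with_seed(13, {
    p <- stats::runif(3)
    q <- stats::runif(3)
  })
  m <- make_manual_model(alphabet, p, q)
  for (k in 1:4) {
    combos <- expand.grid(rep(list(seq_along(alphabet)), k))
    for (r in seq_len(nrow(combos))) {
      idx <- as.integer(combos[r, ])
      expect_equal(
        score_name(m, alphabet[idx]),
        oracle_priority_score(p[idx], q[idx]),
        tolerance = 1e-12
      )
    }
  }
})

test_that("priority weights sum to one and scores stay within p bounds", {
  withr::with_seed(17, {
    for (trial in 1:30) {
      k <- sample(1:6, 1)
      p <- stats::runif(k)
      q <- stats::runif(k)
      toks <- paste0("tok", seq_len(k))
      m <- make_manual_model(toks, p, q)
      s <- score_name(m, toks)
      expect_gte(s, min(p) - 1e-12)
      expect_lte(s, max(p) + 1e-12)
      # brute-force weight expansion sums to 1
      w <- vapply(seq_len(k), function(i) {
        qp <- if (i == 1) 1 else q[i]
        qp * prod(1 - q[seq_len(k) > i])
      }, numeric(1))
      expect_equal(sum(w), 1, tolerance = 1e-12)
    }
  })
})

test_that("increasing a token's p weakly increases every score containing it", {
  withr::with_seed(19, {
    p <- stats::runif(3)
    q <- stats::runif(3)
  })
  toks <- c("a", "b", "c")
  m_lo <- make_manual_model(toks, p, q)
  p_hi <- p
  p_hi[2] <- min(1, p[2] + 0.3)
  m_hi <- make_manual_model(toks, p_hi, q)
  seqs <- list(c("a", "b"), c("b", "c"), c("a", "b", "c"), c("c", "b", "a"), "b")
  for (s in seqs) {
    expect_gte(score_name(m_hi, s), score_name(m_lo, s))
  }
})

test_that("training drives single-token names to their class frequencies", {
  m <- priority_model(rep("kinase", 5), rep("table", 5))
  stats <- tidy(m)
  expect_gt(stats$p[stats$token == "kinase"], 0.9)
  expect_lt(stats$p[stats$token == "table"], 0.1)
  # identical content in both classes: shared tokens sit near 0.5
  m2 <- priority_model(c("alpha beta"), c("alpha beta"))
  expect_equal(score_name(m2, c("alpha", "beta")), 0.5, tolerance = 0.05)
})

test_that("trained model separates synthetic gene names from common words", {
  syn <- synthetic_corpus(n_docs = 10, seed = 1)
  genes <- syn$gene_lexicon
  common <- c(
    "the", "results", "show", "that", "protein", "binding", "was",
    "measured", "in", "cells", "table", "figure", "method", "analysis",
    "study", "data", "model", "test", "values", "mean"
  )
  withr::with_seed(1, {
    pos <- tolower(sample(genes, 200, replace = TRUE))
    neg <- sample(common, 200, replace = TRUE)
  })
  train_idx <- 1:150
  m <- priority_model(pos[train_idx], neg[train_idx])
  held_pos <- vapply(pos[-train_idx], function(x) score_name(m, x), numeric(1))
  held_neg <- vapply(neg[-train_idx], function(x) score_name(m, x), numeric(1))
  # rank-sum AUC on held-out names
  auc <- mean(outer(held_pos, held_neg, ">") + 0.5 * outer(held_pos, held_neg, "=="))
  expect_gt(auc, 0.95)
})

test_that("all-numeric candidates are rejected regardless of score", {
  m <- make_manual_model("1234", p = 1, q = 0.5)
  sentences <- list(c("1234", "binds", "abc1"))
  out <- tag_mentions(
    m, sentences,
    tibble::tibble(sentence_index = 0L, start = 0L, end = 1L)
  )
  expect_equal(nrow(out), 0)
})

test_that("high-scoring candidates are accepted and overlap resolves leftmost-longest", {
  m <- make_manual_model(c("abc1", "def2", "ghi3"), p = c(1, 1, 1), q = rep(0.5, 3))
  sentences <- list(c("abc1", "def2", "ghi3"))
  cands <- tibble::tibble(
    sentence_index = c(0L, 0L), start = c(0L, 1L), end = c(2L, 3L)
  )
  out <- tag_mentions(m, sentences, cands, doc_id = "d")
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 0L)
  expect_equal(out$end, 2L)
  expect_equal(out$text, "abc1 def2")
  # empty candidate list is fine
  expect_equal(nrow(tag_mentions(m, sentences, NULL)), 0)
})

test_that("priority model serialization round-trips", {
  m <- priority_model(c("insulin receptor", "p53"), c("heavy table", "blue chair"))
  path <- withr::local_tempfile()
  write_priority_model(m, path)
  back <- read_priority_model(path)
  expect_equal(back$stats, m$stats, tolerance = 1e-12)
  expect_equal(back$default_p, m$default_p)
  expect_equal(back$decision_threshold, m$decision_threshold)
})
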