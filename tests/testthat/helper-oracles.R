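# Brute-force oracles and fixture builders, kept independent of the
# implementation paths they check.

# Recursive definition of the right-priority score: the rightmost token
# decides with probability q, otherwise the left prefix decides.
oracle_priority_score <- function(p, q) {
  k <- length(p)
  if (k == 1) {
    return(p[1])
  }
  q[k] * p[k] + (1 - q[k]) * oracle_priority_score(p[-k], q[-k])
}

# Literal definition loop: mean of precision at the ranks of relevant docs.
oracle_average_precision <- function(rel) {
  ranks <- which(rel)
  mean(vapply(ranks, function(r) sum(rel[1:r]) / r, numeric(1)))
}

# Literal interpolated-precision area: ip(r) = max precision at recall >= r,
# averaged at each relevant document's recall point.
oracle_auc_ipr <- function(rel) {
  n <- length(rel)
  prec <- cumsum(rel) / seq_len(n)
  ranks <- which(rel)
  ip <- vapply(ranks, function(r) max(prec[r:n]), numeric(1))
  mean(ip)
}

# Central finite differences of a scalar function.
numeric_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x))
    e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# 1-D linearly separable toy: positives have feature 1 active, negatives are
# empty vectors.
make_separable_toy <- function(n_pos = 5, n_neg = 5) {
  list(
    vectors = c(
      replicate(n_pos, 1L, simplify = FALSE),
      replicate(n_neg, integer(0), simplify = FALSE)
    ),
    labels = c(rep(1L, n_pos), rep(-1L, n_neg))
  )
}

# XOR-structured vectors: the label depends on features 3 and 7 jointly
# (+1 iff exactly one is active), never on any singleton. Features 1, 2, 4,
# 5, 6 are label-independent noise.
make_xor_data <- function(n = 200, seed = 42) {
  withr::with_seed(seed, {
    x3 <- stats::rbinom(n, 1, 0.5)
    x7 <- stats::rbinom(n, 1, 0.5)
    noise <- matrix(stats::rbinom(n * 5, 1, 0.15), nrow = n)
    vectors <- lapply(seq_len(n), function(i) {
      idx <- c(
        which(noise[i, ] == 1)[which(noise[i, ] == 1) <= 2],
        if (x3[i] == 1) 3L,
        which(noise[i, ] == 1)[which(noise[i, ] == 1) > 2] + 1L,
        if (x7[i] == 1) 7L
      )
      sort(unique(as.integer(idx)))
    })
    list(
      vectors = vectors,
      labels = ifelse(x3 + x7 == 1, 1L, -1L),
      pair = c(3L, 7L)
    )
  })
}

# Split a synthetic corpus into train/test by position within each class
# (deterministic, stratified).
split_synthetic <- function(syn, train_fraction = 0.75) {
  pick <- function(ids) {
    n_train <- floor(length(ids) * train_fraction)
    ids[seq_len(n_train)]
  }
  train_ids <- c(
    pick(syn$labels$doc_id[syn$labels$label == 1L]),
    pick(syn$labels$doc_id[syn$labels$label == -1L])
  )
  subset_ids <- function(ids) {
    list(
      documents = syn$documents[syn$documents$doc_id %in% ids, ],
      labels = syn$labels[syn$labels$doc_id %in% ids, ],
      parses = syn$parses[syn$parses$doc_id %in% ids, ],
      mentions = syn$mentions[syn$mentions$doc_id %in% ids, ]
    )
  }
  list(
    train = subset_ids(train_ids),
    test = subset_ids(setdiff(syn$labels$doc_id, train_ids))
  )
}

# Random binary relevance vector with at least one positive.
random_ranking <- function(n = 20) {
  rel <- stats::rbinom(n, 1, 0.4) == 1
  if (!any(rel)) rel[sample.int(n, 1)] <- TRUE
  rel
}
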