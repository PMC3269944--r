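# Classification and ranking metrics against their definitional oracles.

test_that("confusion counting over id-keyed labels", {
  gold <- tibble::tibble(doc_id = c("1"), label = 1L)
  pred <- tibble::tibble(doc_id = c("1"), label = 1L)
  x <- confusion_matrix(gold, pred)
  expect_equal(c(x$tp, x$fp, x$fn, x$tn), c(1, 0, 0, 0))

  gold2 <- tibble::tibble(doc_id = c("1", "2"), label = c(1L, -1L))
  pred2 <- tibble::tibble(doc_id = c("2", "1"), label = c(-1L, -1L))
  x2 <- confusion_matrix(gold2, pred2)
  expect_equal(c(x2$tp, x2$fp, x2$fn, x2$tn), c(0, 0, 1, 1))

  expect_error(
    confusion_matrix(gold2, tibble::tibble(doc_id = "3", label = 1L)),
    "mismatch"
  )
})

test_that("all-negative predictions count the imbalanced test-set split", {
  n <- 6000
  n_pos <- 910
  gold <- tibble::tibble(
    doc_id = as.character(1:n),
    label = c(rep(1L, n_pos), rep(-1L, n - n_pos))
  )
  pred <- tibble::tibble(doc_id = gold$doc_id, label = rep(-1L, n))
  x <- confusion_matrix(gold, pred)
  expect_equal(x$fn, 910)
  expect_equal(x$tn, 5090)
  suppressWarnings(expect_equal(basic_rates(x)$accuracy, 5090 / 6000))
})

test_that("degenerate denominators give NaN rates and zero F1/MCC", {
  x <- confusion_counts(1, 0, 0, 0)
  suppressWarnings(r <- basic_rates(x))
  expect_equal(r$accuracy, 1)
  expect_equal(r$precision, 1)
  expect_equal(r$sensitivity, 1)
  expect_true(is.nan(r$specificity))
  expect_equal(mcc_score(x), 0) # zero denominator factor
  expect_equal(f1_score(confusion_counts(0, 0, 5, 5)), 0)
})

test_that("f1 equals the harmonic mean of precision and recall; P=R gives F1=P", {
  withr::with_seed(47, {
    for (trial in 1:20) {
      x <- confusion_counts(
        sample(1:50, 1), sample(0:50, 1), sample(0:50, 1), sample(1:50, 1)
      )
      suppressWarnings(r <- basic_rates(x))
      if (!is.nan(r$precision) && !is.nan(r$sensitivity) &&
            r$precision + r$sensitivity > 0) {
        expect_equal(
          f1_score(x),
          2 * r$precision * r$sensitivity / (r$precision + r$sensitivity)
        )
      }
    }
  })
  x <- confusion_counts(10, 5, 5, 20) # P = R = 2/3
  expect_equal(f1_score(x), 2 / 3)
})

test_that("mcc is 1 for perfect prediction and flips sign under inversion", {
  expect_equal(mcc_score(confusion_counts(10, 0, 0, 20)), 1)
  withr::with_seed(53, {
    for (trial in 1:20) {
      x <- confusion_counts(sample(1:40, 1), sample(1:40, 1), sample(1:40, 1), sample(1:40, 1))
      inv <- confusion_counts(x$fn, x$tn, x$tp, x$fp) # invert predictions
      expect_equal(mcc_score(inv), -mcc_score(x), tolerance = 1e-12)
    }
  })
})

test_that("average precision matches hand enumeration and its oracle", {
  expect_equal(average_precision(c(TRUE, FALSE, TRUE)), (1 + 2 / 3) / 2)
  expect_equal(average_precision(c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_error(average_precision(c(FALSE, FALSE)), "relevant")
  withr::with_seed(59, {
    for (trial in 1:100) {
      rel <- random_ranking(20)
      expect_equal(average_precision(rel), oracle_average_precision(rel))
    }
  })
})

test_that("auc_ipr matches hand enumeration, its oracle, and dominates AP", {
  expect_equal(auc_ipr(c(TRUE, FALSE, TRUE)), (1 + 2 / 3) / 2)
  expect_equal(auc_ipr(c(FALSE, TRUE)), 0.5)
  withr::with_seed(61, {
    for (trial in 1:100) {
      rel <- random_ranking(20)
      expect_equal(auc_ipr(rel), oracle_auc_ipr(rel))
      expect_gte(auc_ipr(rel), average_precision(rel) - 1e-12)
    }
  })
})

test_that("precision at rank n", {
  expect_equal(precision_at(c(TRUE, TRUE, FALSE, FALSE), 2), 1)
  expect_equal(precision_at(c(FALSE, FALSE), 2), 0)
  expect_equal(precision_at(c(TRUE, FALSE, TRUE, FALSE), 3), 2 / 3)
  expect_error(precision_at(c(TRUE, FALSE), 3), "between")
})

test_that("ranking metrics ignore score changes that preserve the order", {
  scores <- tibble::tibble(
    doc_id = c("a", "b", "c", "d"),
    score = c(4, 3, 2, 1), label = c(1L, -1L, 1L, -1L)
  )
  gold <- tibble::tibble(doc_id = c("a", "b", "c", "d"),
                         label = c(1L, -1L, 1L, -1L))
  m1 <- evaluate_scores(scores, gold)
  scores2 <- scores
  scores2$score <- c(400, 30, 2.5, 0.1)
  m2 <- evaluate_scores(scores2, gold)
  expect_equal(
    m1$value[m1$metric == "average_precision"],
    m2$value[m2$metric == "average_precision"]
  )
  expect_equal(
    m1$value[m1$metric == "auc_ipr"],
    m2$value[m2$metric == "auc_ipr"]
  )
})

test_that("score ties break by ascending doc_id, deterministically", {
  scores <- tibble::tibble(
    doc_id = c("b", "a"), score = c(1, 1), label = c(1L, 1L)
  )
  gold <- tibble::tibble(doc_id = c("a", "b"), label = c(1L, -1L))
  # tie at score 1: "a" ranks before "b", and "a" is the positive
  m <- evaluate_scores(scores, gold)
  expect_equal(m$value[m$metric == "average_precision"], 1)
})

test_that("pr_curve tracks precision/recall and the interpolated envelope", {
  scores <- tibble::tibble(doc_id = c("a", "b", "c"), score = c(3, 2, 1))
  gold <- tibble::tibble(doc_id = c("a", "b", "c"), label = c(1L, -1L, 1L))
  curve <- pr_curve(scores, gold)
  expect_equal(curve$precision, c(1, 1 / 2, 2 / 3))
  expect_equal(curve$recall, c(1 / 2, 1 / 2, 1))
  expect_equal(curve$interpolated, c(1, 2 / 3, 2 / 3))
})
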