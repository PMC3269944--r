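# Modified Huber loss, regularization, and the gradient-descent fit.

test_that("loss pieces take their closed-form values and meet at z = -1", {
  expect_equal(modified_huber_loss(2), 0)
  expect_equal(modified_huber_loss(0), 1)
  # both branches agree at the seam
  expect_equal(-4 * (-1), 4)
  expect_equal((1 - (-1))^2, 4)
  expect_equal(modified_huber_loss(-1), 4)
})

test_that("loss is convex, non-increasing, and C1 on a grid", {
  z <- seq(-3, 3, by = 0.01)
  h <- modified_huber_loss(z)
  expect_true(all(diff(h) <= 1e-12)) # non-increasing
  expect_true(all(diff(diff(h)) >= -1e-9)) # convex
  # numerical derivative matches the analytic one away from grid artifacts
  num <- (modified_huber_loss(z + 1e-6) - modified_huber_loss(z - 1e-6)) / 2e-6
  expect_equal(num, ppitriage:::modified_huber_deriv(z), tolerance = 1e-5)
})

test_that("lambda follows the mean-norm formula", {
  # norms 2 and 4 -> mean 3 -> lambda = 0.0005 * 9
  expect_equal(compute_lambda(list(1:4, 1:16), 5e-4), 0.0045)
  expect_equal(compute_lambda(list(1:4, 1:16), 0), 0)
  expect_equal(compute_lambda(list(1L), 1), 1)
  expect_warning(lam <- compute_lambda(list(integer(0)), 5e-4), "empty")
  expect_equal(lam, 0)
})

test_that("analytic cost gradient matches central finite differences", {
  withr::with_seed(23, {
    n <- 12
    V <- 6
    vectors <- lapply(seq_len(n), function(i) sort(sample.int(V, sample(1:4, 1))))
    y <- sample(c(-1L, 1L), n, replace = TRUE)
    y[1] <- 1L
    y[2] <- -1L
    par0 <- stats::rnorm(V + 1) * 0.5
  })
  X <- ppitriage:::vectors_to_matrix(vectors, V)
  lambda <- compute_lambda(vectors, 5e-4)
  cost <- function(par) {
    w <- par[1:V]
    theta <- par[V + 1]
    z <- y * (as.vector(X %*% w) + theta)
    sum(modified_huber_loss(z)) + lambda * sum(w^2)
  }
  grad_analytic <- function(par) {
    w <- par[1:V]
    theta <- par[V + 1]
    z <- y * (as.vector(X %*% w) + theta)
    hp <- ppitriage:::modified_huber_deriv(z) * y
    c(as.vector(Matrix::crossprod(X, hp)) + 2 * lambda * w, sum(hp))
  }
  g_num <- numeric_gradient(cost, par0)
  g_ana <- grad_analytic(par0)
  expect_equal(g_ana, g_num, tolerance = 1e-5)
})

test_that("cost is non-increasing across accepted iterations", {
  withr::with_seed(29, {
    vectors <- lapply(1:40, function(i) sort(sample.int(15, sample(1:6, 1))))
    y <- sample(c(-1L, 1L), 40, replace = TRUE)
    y[1:2] <- c(1L, -1L)
  })
  fit <- huber_fit(vectors, y, n_features = 15)
  expect_true(all(diff(fit$cost_trace) <= 1e-12))
  expect_lte(fit$final_cost, fit$cost_trace[1])
})

test_that("separable toy reaches zero training error and unit margins", {
  toy <- make_separable_toy()
  fit <- huber_fit(
    toy$vectors, toy$labels, n_features = 1, lambda_prime = 0,
    settings = train_settings(max_iterations = 2000, tolerance = 1e-14)
  )
  pred <- huber_classify(fit, toy$vectors)
  expect_equal(pred, toy$labels)
  z <- toy$labels * huber_score(fit, toy$vectors)
  expect_true(all(z >= 1 - 1e-4))
  cmat <- confusion_matrix(toy$labels, pred)
  expect_equal(f1_score(cmat), 1)
})

test_that("label-flipped training negates the weights", {
  withr::with_seed(31, {
    vectors <- lapply(1:20, function(i) sort(sample.int(8, sample(1:4, 1))))
    y <- sample(c(-1L, 1L), 20, replace = TRUE)
    y[1:2] <- c(1L, -1L)
  })
  fit_a <- huber_fit(vectors, y, n_features = 8)
  fit_b <- huber_fit(vectors, -y, n_features = 8)
  expect_equal(fit_b$w, -fit_a$w, tolerance = 1e-6)
  expect_equal(abs(fit_b$theta), abs(fit_a$theta), tolerance = 1e-6)
})

test_that("the fit is invariant to training-example order", {
  withr::with_seed(37, {
    vectors <- lapply(1:25, function(i) sort(sample.int(10, sample(1:5, 1))))
    y <- sample(c(-1L, 1L), 25, replace = TRUE)
    y[1:2] <- c(1L, -1L)
    perm <- sample.int(25)
  })
  fit_a <- huber_fit(vectors, y, n_features = 10)
  fit_b <- huber_fit(vectors[perm], y[perm], n_features = 10)
  expect_equal(fit_a$w, fit_b$w, tolerance = 1e-10)
  expect_equal(fit_a$theta, fit_b$theta, tolerance = 1e-10)
})

test_that("scores and sign classification follow the stated conventions", {
  model <- structure(
    list(
      w = c(0, 0), theta = 0.3, lambda = 0, lambda_prime = 0,
      n_features = 2, iterations = 0L, final_cost = 0,
      cost_trace = numeric(0), converged = TRUE, mean_loss = FALSE,
      settings = NULL
    ),
    class = "huber_fit"
  )
  expect_equal(huber_score(model, list(1:2, integer(0))), c(0.3, 0.3))
  expect_equal(huber_classify(model, list(1:2)), 1L)
  model$theta <- -0.7
  expect_equal(huber_classify(model, list(1:2)), -1L)
  model$theta <- 0 # score exactly 0 predicts the negative class
  expect_equal(huber_classify(model, list(integer(0))), -1L)
})

test_that("single-class input is rejected", {
  expect_error(
    huber_fit(list(1L, 2L), c(1L, 1L), n_features = 2),
    "both classes"
  )
})

test_that("huber model serialization round-trips, and tidy/glance report the fit", {
  toy <- make_separable_toy()
  fit <- huber_fit(
    toy$vectors, toy$labels, n_features = 3,
    settings = train_settings(max_iterations = 2000, tolerance = 1e-6)
  )
  path <- withr::local_tempfile()
  write_huber_model(fit, path)
  back <- read_huber_model(path)
  expect_equal(back$w, fit$w)
  expect_equal(back$theta, fit$theta)
  expect_equal(back$lambda, fit$lambda)
  td <- tidy(fit)
  expect_equal(nrow(td), 3)
  gl <- glance(fit)
  expect_equal(gl$theta, fit$theta)
  expect_true(gl$converged)
})
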