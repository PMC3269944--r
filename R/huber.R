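# Large-margin linear classifier under the modified Huber loss.
#
# Cost: C(w, theta) = sum_i h(y_i (w.X_i + theta)) + lambda ||w||^2, with
# lambda = lambda_prime * <|x|>^2 derived from the mean Euclidean norm of the
# training vectors. Minimized by deterministic full-batch gradient descent
# with backtracking line search from w = 0, theta = 0.

#' Modified Huber loss
#'
#' A convex, continuously differentiable margin loss: linear (`-4z`) for
#' badly misclassified points (`z < -1`), quadratic `(1 - z)^2` near the
#' margin (`-1 <= z < 1`), and zero beyond it (`z >= 1`). Both pieces meet
#' at `z = -1` with value 4 and slope -4.
#'
#' @param z Margin values `y * (w.x + theta)` (vectorized).
#' @return Non-negative loss values.
#' @examples
#' modified_huber_loss(c(-2, -1, 0, 1, 2))
#' @export
modified_huber_loss <- function(z) {
  ifelse(z < -1, -4 * z, ifelse(z < 1, (1 - z)^2, 0))
}

# First derivative: -4 for z < -1, 2(z - 1) for -1 <= z < 1, 0 for z >= 1.
modified_huber_deriv <- function(z) {
  ifelse(z < -1, -4, ifelse(z < 1, 2 * (z - 1), 0))
}

#' Data-derived regularization weight
#'
#' `lambda = lambda_prime * <|x|>^2` where `<|x|>` is the mean Euclidean norm
#' of the training feature vectors; for binary vectors the norm is the square
#' root of the active-feature count. An alternative normalization dividing by
#' the training-set size is available via `per_example`.
#'
#' @param vectors List of integer index vectors (binary features).
#' @param lambda_prime Base regularization rate (default 0.0005).
#' @param per_example If `TRUE`, divide by the number of training vectors.
#' @return Scalar `lambda >= 0`.
#' @export
compute_lambda <- function(vectors, lambda_prime = 5e-4, per_example = FALSE) {
  stopifnot(length(vectors) > 0)
  norms <- sqrt(lengths(vectors))
  if (all(norms == 0)) {
    warn("all training vectors are empty; lambda = 0")
    return(0)
  }
  lam <- lambda_prime * mean(norms)^2
  if (per_example) lam <- lam / length(vectors)
  lam
}

#' Training settings for the Huber classifier
#'
#' @param max_iterations Cap on accepted gradient-descent iterations.
#' @param initial_rate Initial step size for backtracking line search.
#' @param backtrack Step-shrink factor in `(0, 1)`.
#' @param tolerance Relative cost-change convergence threshold.
#' @param seed Recorded for provenance; batch descent itself uses no
#'   randomness.
#' @return A list of class `train_settings`.
#' @export
train_settings <- function(max_iterations = 500, initial_rate = 1,
                           backtrack = 0.5, tolerance = 1e-8, seed = NULL) {
  stopifnot(max_iterations >= 1, tolerance > 0, backtrack > 0, backtrack < 1)
  structure(
    list(
      max_iterations = as.integer(max_iterations),
      initial_rate = initial_rate, backtrack = backtrack,
      tolerance = tolerance, seed = seed
    ),
    class = "train_settings"
  )
}

#' Fit the modified-Huber large-margin classifier
#'
#' Minimizes `sum_i h(y_i (w.X_i + theta)) + lambda ||w||^2` over the weight
#' vector `w` and threshold `theta` by full-batch gradient descent with
#' backtracking line search, starting from zero. The fit is deterministic
#' and invariant to the order of the training examples. Setting `mean_loss =
#' TRUE` switches the data term to the per-example mean.
#'
#' @param vectors List of sorted integer index vectors, or a sparse
#'   `dgCMatrix` of documents x features.
#' @param labels Integer vector in `{+1, -1}`; both classes must be present.
#' @param n_features Vocabulary size (inferred from the data when missing —
#'   pass it explicitly so trailing never-active features keep a weight).
#' @param lambda_prime Base regularization rate, default 0.0005.
#' @param settings A [train_settings()].
#' @param mean_loss Use the mean rather than the sum of losses.
#' @param per_example_lambda Passed to [compute_lambda()].
#' @return An object of class `huber_fit`: weights `w`, threshold `theta`,
#'   `lambda`, `lambda_prime`, iteration count, the cost trace, and
#'   convergence status.
#' @export
huber_fit <- function(vectors, labels, n_features = NULL,
                      lambda_prime = 5e-4, settings = train_settings(),
                      mean_loss = FALSE, per_example_lambda = FALSE) {
  if (is.list(vectors)) {
    if (is.null(n_features)) {
      n_features <- max(c(0L, unlist(vectors)))
    }
    X <- vectors_to_matrix(vectors, n_features)
    lambda <- compute_lambda(vectors, lambda_prime, per_example_lambda)
  } else {
    X <- vectors
    n_features <- ncol(X)
    norms <- sqrt(Matrix::rowSums(X^2))
    lambda <- lambda_prime * mean(norms)^2
    if (per_example_lambda) lambda <- lambda / nrow(X)
  }
  y <- as.integer(labels)
  T_n <- length(y)
  stopifnot(T_n >= 2, nrow(X) == T_n)
  if (!all(y %in% c(-1L, 1L))) {
    abort("labels must be +1 or -1")
  }
  if (length(unique(y)) < 2) {
    abort("training requires both classes to be present")
  }
  scale_term <- if (mean_loss) 1 / T_n else 1

  cost_fn <- function(w, theta) {
    z <- y * (as.vector(X %*% w) + theta)
    scale_term * sum(modified_huber_loss(z)) + lambda * sum(w^2)
  }
  grad_fn <- function(w, theta) {
    z <- y * (as.vector(X %*% w) + theta)
    hp <- modified_huber_deriv(z) * y
    gw <- scale_term * as.vector(Matrix::crossprod(X, hp)) + 2 * lambda * w
    gt <- scale_term * sum(hp)
    list(w = gw, theta = gt)
  }

  w <- numeric(n_features)
  theta <- 0
  cost <- cost_fn(w, theta)
  trace <- cost
  step <- settings$initial_rate
  iterations <- 0L
  converged <- FALSE

  for (it in seq_len(settings$max_iterations)) {
    g <- grad_fn(w, theta)
    gnorm2 <- sum(g$w^2) + g$theta^2
    if (gnorm2 == 0) {
      converged <- TRUE
      break
    }
    # backtracking line search with an Armijo sufficient-decrease condition
    accepted <- FALSE
    s <- step
    for (bt in 1:60) {
      w_new <- w - s * g$w
      theta_new <- theta - s * g$theta
      cost_new <- cost_fn(w_new, theta_new)
      if (cost_new <= cost - 1e-4 * s * gnorm2) {
        accepted <- TRUE
        break
      }
      s <- s * settings$backtrack
    }
    if (!accepted) {
      if (cost_new <= cost * (1 + 1e-12)) {
        converged <- TRUE # stationary: no direction improves the cost
        break
      }
      abort(paste0(
        "gradient descent failed to decrease the cost at iteration ", it,
        " (backtracking exhausted)"
      ))
    }
    rel <- (cost - cost_new) / max(cost, .Machine$double.eps)
    w <- w_new
    theta <- theta_new
    cost <- cost_new
    trace <- c(trace, cost)
    iterations <- it
    step <- s * 2 # allow the step to grow back
    if (rel < settings$tolerance) {
      converged <- TRUE
      break
    }
  }

  structure(
    list(
      w = w, theta = theta, lambda = lambda, lambda_prime = lambda_prime,
      n_features = n_features, iterations = iterations,
      final_cost = cost, cost_trace = trace, converged = converged,
      mean_loss = mean_loss, settings = settings
    ),
    class = "huber_fit"
  )
}

#' Real-valued classifier score
#'
#' `w.x + theta`; higher means more PPI-like. Used directly for ranking.
#'
#' @param model A `huber_fit`.
#' @param vectors List of integer index vectors or a sparse matrix.
#' @return Numeric vector of scores.
#' @export
huber_score <- function(model, vectors) {
  stopifnot(inherits(model, "huber_fit"))
  if (is.list(vectors)) {
    vapply(vectors, function(idx) {
      idx <- idx[idx <= model$n_features]
      sum(model$w[idx]) + model$theta
    }, numeric(1), USE.NAMES = FALSE)
  } else {
    as.vector(vectors %*% model$w) + model$theta
  }
}

#' Binary label from the score sign
#'
#' `sign(score)`, with an exact zero mapped to `-1` (conservative
#' tie-break: an uncommitted document is not flagged as PPI).
#'
#' @inheritParams huber_score
#' @return Integer vector in `{+1, -1}`.
#' @export
huber_classify <- function(model, vectors) {
  ifelse(huber_score(model, vectors) > 0, 1L, -1L)
}

#' @export
print.huber_fit <- function(x, ...) {
  cat(
    "Modified-Huber linear classifier:", x$n_features, "features; lambda =",
    format(x$lambda, digits = 4), "(lambda' =", x$lambda_prime, ")\n",
    x$iterations, "iterations; final cost", format(x$final_cost, digits = 6),
    if (x$converged) "(converged)\n" else "(iteration cap reached)\n"
  )
  invisible(x)
}

#' Broom-style accessors for fitted objects
#'
#' `tidy()` returns one row per model term; `glance()` one row of fit
#' summaries.
#'
#' @param x A fitted object.
#' @param vocabulary Optional `ppi_vocabulary` to attach feature strings.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_ppitriage
NULL

#' @rdname tidy_ppitriage
#' @method tidy huber_fit
#' @export
tidy.huber_fit <- function(x, vocabulary = NULL, ...) {
  out <- tibble(index = seq_len(x$n_features), weight = x$w)
  if (!is.null(vocabulary)) {
    out$feature <- vocabulary$feature[match(out$index, vocabulary$index)]
    out <- out[, c("index", "feature", "weight")]
  }
  out
}

#' @rdname tidy_ppitriage
#' @method glance huber_fit
#' @export
glance.huber_fit <- function(x, ...) {
  tibble(
    n_features = x$n_features, lambda = x$lambda,
    lambda_prime = x$lambda_prime, theta = x$theta,
    iterations = x$iterations, final_cost = x$final_cost,
    converged = x$converged
  )
}

#' Serialize / deserialize a Huber classifier
#'
#' Header line with `theta`, `lambda`, `lambda_prime` and the vocabulary
#' size, then a TSV of `(index, weight)` for nonzero weights.
#'
#' @param model A `huber_fit`.
#' @param path File path.
#' @return `write_huber_model()` returns `path` invisibly;
#'   `read_huber_model()` the model.
#' @export
write_huber_model <- function(model, path) {
  header <- sprintf(
    "#huber_model\ttheta=%.17g\tlambda=%.17g\tlambda_prime=%.17g\tn_features=%d",
    model$theta, model$lambda, model$lambda_prime, model$n_features
  )
  nz <- which(model$w != 0)
  writeLines(c(header, sprintf("%d\t%.17g", nz, model$w[nz])), path)
  invisible(path)
}

#' @rdname write_huber_model
#' @export
read_huber_model <- function(path) {
  lines <- read_input_lines(path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  getval <- function(key) {
    as.numeric(sub(paste0(key, "="), "", hdr[startsWith(hdr, paste0(key, "="))]))
  }
  n_features <- as.integer(getval("n_features"))
  w <- numeric(n_features)
  if (length(lines) > 1) {
    parts <- strsplit(lines[-1], "\t", fixed = TRUE)
    idx <- as.integer(vapply(parts, `[[`, character(1), 1))
    w[idx] <- as.numeric(vapply(parts, `[[`, character(1), 2))
  }
  structure(
    list(
      w = w, theta = getval("theta"), lambda = getval("lambda"),
      lambda_prime = getval("lambda_prime"), n_features = n_features,
      iterations = NA_integer_, final_cost = NA_real_,
      cost_trace = numeric(0), converged = NA, mean_loss = FALSE,
      settings = NULL
    ),
    class = "huber_fit"
  )
}
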