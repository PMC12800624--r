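#' Fit a canonical linear discriminant model
#'
#' Classical DFA: pooled within-class covariance on the `N - g` denominator,
#' discriminant axes the leading eigenvectors of `W^-1 B` (at most `g - 1`),
#' each scaled to unit pooled within-class variance. Classification assigns
#' a point to the class minimising the Mahalanobis distance to the class
#' mean adjusted by the log prior (uniform priors by default). A ridge term
#' `1e-8 * mean(diag(W))` is added when `W` is near-singular (condition
#' number above 1e10), with a warning.
#'
#' @param table Data frame with a `context` column (the class label).
#' @param features Numeric feature columns to use.
#' @param priors `NULL` for uniform, `"proportional"` for class proportions,
#'   or a named numeric vector.
#' @return An object of class `dfa_model`.
#' @export
fit_dfa <- function(table, features, priors = NULL) {
  y <- factor(table$context)
  X <- as.matrix(table[features])
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop_invalid("features must be numeric and complete")
  g <- nlevels(y)
  if (g < 2) stop_invalid("need at least 2 classes")
  counts <- table(y)
  if (any(counts < 2)) stop_invalid("every class needs more than 1 row")
  n <- nrow(X); p <- ncol(X)

  means <- do.call(rbind, lapply(levels(y), function(l)
    colMeans(X[y == l, , drop = FALSE])))
  rownames(means) <- levels(y)
  center <- colMeans(X)

  W <- matrix(0, p, p)
  for (l in levels(y)) {
    Xc <- sweep(X[y == l, , drop = FALSE], 2, means[l, ])
    W <- W + crossprod(Xc)
  }
  W <- W / (n - g)
  if (kappa(W) > 1e10) {
    warning("near-singular within-class covariance; adding ridge term")
    W <- W + diag(1e-8 * mean(diag(W)), p)
  }
  B <- matrix(0, p, p)
  for (l in levels(y)) {
    d <- means[l, ] - center
    B <- B + counts[[l]] * tcrossprod(d)
  }
  ev <- eigen(solve(W, B))
  ord <- order(Re(ev$values), decreasing = TRUE)[seq_len(min(g - 1, p))]
  scaling <- Re(ev$vectors[, ord, drop = FALSE])
  eigenvalues <- Re(ev$values[ord])
  # unit pooled within-class variance along each axis
  for (j in seq_len(ncol(scaling))) {
    s2 <- drop(t(scaling[, j]) %*% W %*% scaling[, j])
    if (s2 > 0) scaling[, j] <- scaling[, j] / sqrt(s2)
  }
  colnames(scaling) <- paste0("LD", seq_len(ncol(scaling)))
  rownames(scaling) <- features

  pr <- if (is.null(priors)) {
    setNames(rep(1 / g, g), levels(y))
  } else if (identical(priors, "proportional")) {
    setNames(as.numeric(counts) / n, levels(y))
  } else {
    stopifnot(all(levels(y) %in% names(priors)))
    priors[levels(y)] / sum(priors[levels(y)])
  }

  structure(list(classes = levels(y), means = means, W = W,
                 Winv = solve(W), priors = pr, scaling = scaling,
                 eigenvalues = eigenvalues, center = center,
                 features = features, counts = as.vector(counts)),
            class = "dfa_model")
}

#' Predict from a discriminant model
#'
#' @param object A `dfa_model`.
#' @param newdata Data frame containing the model's feature columns.
#' @param ... Unused.
#' @return List with `class` (factor; ties broken towards the lowest class
#'   index), `posterior` (matrix), `scores` (discriminant scores on the
#'   centred data) and `d2` (squared Mahalanobis distances).
#' @export
predict.dfa_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata[object$features])
  storage.mode(X) <- "double"
  d2 <- sapply(object$classes, function(l) {
    Xc <- sweep(X, 2, object$means[l, ])
    rowSums((Xc %*% object$Winv) * Xc)
  })
  d2 <- matrix(d2, nrow = nrow(X), dimnames = list(NULL, object$classes))
  disc <- sweep(-0.5 * d2, 2, log(object$priors), `+`)
  pred <- apply(disc, 1, function(r) which(r == max(r))[1])  # tie: lowest index
  post <- exp(disc - apply(disc, 1, max))
  post <- post / rowSums(post)
  scores <- sweep(X, 2, object$center) %*% object$scaling
  list(class = factor(object$classes[pred], levels = object$classes),
       posterior = post, scores = scores, d2 = d2)
}

#' Leave-one-out cross-validated classification
#'
#' For each row, the discriminant model is refit on all remaining rows and
#' the held-out row is predicted and scored. Folds whose training set would
#' leave a class with fewer than two rows are flagged and excluded from the
#' denominators.
#'
#' @inheritParams fit_dfa
#' @return An object of class `loocv_result`: `predictions` (per-call data
#'   frame with true/predicted labels and held-out LD scores), `confusion`
#'   (true x predicted counts), `class_props` (per-class correct
#'   proportions), `total_prop`, `n_flagged`.
#' @export
classify_loocv <- function(table, features, priors = NULL) {
  y <- factor(table$context)
  n <- nrow(table)
  preds <- character(n); flagged <- logical(n)
  scores <- matrix(NA_real_, n, nlevels(y) - 1)
  for (i in seq_len(n)) {
    train <- table[-i, , drop = FALSE]
    if (any(table(factor(train$context, levels = levels(y))) < 2)) {
      flagged[i] <- TRUE
      preds[i] <- NA_character_
      next
    }
    m <- fit_dfa(train, features, priors = priors)
    pr <- predict(m, table[i, , drop = FALSE])
    preds[i] <- as.character(pr$class)
    k <- min(ncol(scores), ncol(pr$scores))
    scores[i, seq_len(k)] <- pr$scores[1, seq_len(k)]
  }
  keep <- !flagged
  confusion <- table(true = factor(table$context[keep], levels = levels(y)),
                     predicted = factor(preds[keep], levels = levels(y)))
  class_props <- diag(confusion) / pmax(rowSums(confusion), 1)
  total_prop <- sum(diag(confusion)) / sum(confusion)
  predictions <- data.frame(
    call_id = table$call_id %||% as.character(seq_len(n)),
    true = as.character(y), predicted = preds,
    correct = preds == as.character(y), flagged = flagged,
    stringsAsFactors = FALSE)
  colnames(scores) <- paste0("LD", seq_len(ncol(scores)))
  structure(list(predictions = cbind(predictions, scores),
                 confusion = confusion, class_props = class_props,
                 total_prop = total_prop, n_flagged = sum(flagged)),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result: total correct %.3f over %d calls (%d flagged)>\n",
              x$total_prop, sum(x$confusion), x$n_flagged))
  print(x$confusion)
  invisible(x)
}

#' Class-proportion chance probabilities
#'
#' Per class, the chance probability of a correct assignment under random
#' classification equals the class's sample proportion; the pooled chance
#' is `1 / g` for `g` classes.
#'
#' @param labels Vector of class labels.
#' @return List of class `chance_model`: `class_probs` (named), `pooled`,
#'   `counts`, `n`.
#' @export
chance_probabilities <- function(labels) {
  labels <- factor(labels)
  if (length(labels) == 0) stop_invalid("labels must be nonempty")
  counts <- table(labels)
  structure(list(class_probs = as.vector(counts) / length(labels),
                 pooled = 1 / nlevels(labels),
                 counts = as.vector(counts), n = length(labels),
                 classes = levels(labels)),
            class = "chance_model")
}

#' Exact binomial test by tail summation
#'
#' `greater`: `p = sum_{j >= k} C(n, j) p0^j (1 - p0)^(n - j)`, evaluated by
#' summing exact binomial masses (log-gamma arithmetic). `two_sided`: the
#' sum of the probabilities of all outcomes no more likely than `k` (the
#' standard exact two-sided method, with the usual `1 + 1e-7` relative
#' tolerance on the mass comparison).
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param p0 Null success probability in `(0, 1)`.
#' @param alternative `"greater"` or `"two_sided"`.
#' @return One-row data frame: k, n, p0, alternative, p_value.
#' @export
binomial_test <- function(k, n, p0, alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  if (!(k >= 0 && k <= n)) stop_invalid("k must be in [0, n]")
  if (!(p0 > 0 && p0 < 1)) stop_invalid("p0 must be in (0, 1)")
  mass <- exp(lchoose(n, 0:n) + (0:n) * log(p0) + (n - (0:n)) * log1p(-p0))
  p <- if (alternative == "greater") {
    sum(mass[(k + 1):(n + 1)])
  } else {
    sum(mass[mass <= mass[k + 1] * (1 + 1e-7)])
  }
  data.frame(k = k, n = n, p0 = p0, alternative = alternative,
             p_value = min(1, p))
}

#' Assess cross-validated classification against chance
#'
#' One exact binomial test per class (successes = correctly assigned calls
#' of that class, null probability = the class's chance proportion) plus a
#' pooled test of the total correct count against `1 / g`.
#'
#' @param loocv A `loocv_result`.
#' @param chance A `chance_model` (default: recomputed from the confusion
#'   matrix margins).
#' @param alternative Passed to [binomial_test].
#' @return Data frame with one row per class plus a `"total"` row: test,
#'   k, n, p0, p_value.
#' @export
assess_classification <- function(loocv, chance = NULL,
                                  alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  cm <- loocv$confusion
  if (is.null(chance)) {
    labs <- rep(rownames(cm), rowSums(cm))
    chance <- chance_probabilities(labs)
  }
  rows <- lapply(seq_along(rownames(cm)), function(i) {
    p0 <- chance$class_probs[match(rownames(cm)[i], chance$classes)]
    bt <- binomial_test(cm[i, i], sum(cm[i, ]), p0, alternative)
    cbind(data.frame(test = rownames(cm)[i], stringsAsFactors = FALSE), bt)
  })
  bt <- binomial_test(sum(diag(cm)), sum(cm), chance$pooled, alternative)
  rows[[length(rows) + 1]] <- cbind(data.frame(test = "total"), bt)
  out <- do.call(rbind, rows)
  out$alternative <- NULL
  attr(out, "alternative") <- alternative
  out
}

#' Variable contributions to the discriminant axes
#'
#' Pearson correlation of each feature with the scores of each discriminant
#' axis, emitted in long format for heatmap plotting. Scores default to the
#' full-data fit; held-out LOOCV scores can be supplied instead.
#'
#' @param table Data frame holding the features.
#' @param features Feature columns.
#' @param model A `dfa_model`.
#' @param scores Optional score matrix (rows matching `table`); default
#'   `predict(model, table)$scores`.
#' @return Data frame of rows (feature, axis, r); zero-variance features
#'   yield `NA` with a warning.
#' @export
contribution_matrix <- function(table, features, model, scores = NULL) {
  scores <- scores %||% predict(model, table)$scores
  rows <- list(); k <- 0L
  for (f in features) {
    v <- table[[f]]
    if (sd(v) == 0)
      warning(sprintf("zero-variance feature: %s (correlations set to NA)", f))
    for (j in seq_len(ncol(scores))) {
      k <- k + 1L
      r <- if (sd(v) == 0 || sd(scores[, j]) == 0) {
        NA_real_
      } else cor(v, scores[, j])
      rows[[k]] <- data.frame(feature = f, axis = colnames(scores)[j], r = r,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
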