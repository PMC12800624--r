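#' Compute the coded response variables from a trial table
#'
#' Gaze and self-directed-behaviour responses are the after-minus-before
#' count differences; the yawn response is the binary presence in the 3-min
#' post-stimulus window. Rows with missing counts are rejected and reported
#' in the `rejected` attribute.
#'
#' @param trials A `behavioral_dataset` (or data frame with its columns).
#' @param floor_at_zero Floor the count differences at zero so that they are
#'   representable by a zero-inflated Poisson response (the default
#'   preprocessing used before [fit_zip_mixed]).
#' @return `trials` with added `gaze_diff`, `sdb_diff` and `yawn_response`
#'   columns.
#' @export
response_differences <- function(trials, floor_at_zero = TRUE) {
  need <- c("gazes_before", "gazes_after", "sdb_before", "sdb_after",
            "yawn_after")
  stopifnot(all(need %in% names(trials)))
  ok <- stats::complete.cases(trials[need])
  rejected <- trials[!ok, , drop = FALSE]
  out <- trials[ok, , drop = FALSE]
  out$gaze_diff <- out$gazes_after - out$gazes_before
  out$sdb_diff <- out$sdb_after - out$sdb_before
  if (floor_at_zero) {
    out$gaze_diff <- pmax(0L, out$gaze_diff)
    out$sdb_diff <- pmax(0L, out$sdb_diff)
  }
  out$yawn_response <- out$yawn_after
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

# Marginal negative log-likelihood of a random-intercept GLMM via
# Gauss-Hermite quadrature. family: "zip" (Poisson with a shared
# zero-inflation probability, intercept-only on the logit scale) or
# "binomial" (Bernoulli-logit). theta = (beta, [zi_logit], log_sigma).
glmm_negloglik <- function(theta, y, X, group_idx, n_groups, gh, family) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]
  zi_logit <- if (family == "zip") theta[p + 1] else NULL
  log_sigma <- theta[length(theta)]
  sigma <- exp(log_sigma)
  eta <- drop(X %*% beta)
  bk <- sqrt(2) * sigma * gh$x            # quadrature abscissae on b scale
  logw <- log(gh$w) - 0.5 * log(pi)
  K <- length(bk)
  logf <- matrix(0, length(y), K)
  if (family == "zip") {
    zi <- stats::plogis(zi_logit)
    for (k in seq_len(K)) {
      lambda <- exp(eta + bk[k])
      lp <- stats::dpois(y, lambda, log = TRUE)
      logf[, k] <- ifelse(y == 0,
                          log(zi + (1 - zi) * exp(-lambda)),
                          log1p(-zi) + lp)
    }
  } else {
    for (k in seq_len(K)) {
      pr <- stats::plogis(eta + bk[k])
      logf[, k] <- ifelse(y == 1, log(pr), log1p(-pr))
    }
  }
  S <- rowsum(logf, group_idx)            # groups x K
  M <- apply(S, 1, max)
  ll <- sum(M + log(rowSums(exp(sweep(S, 1, M) +
                                  matrix(logw, n_groups, K, byrow = TRUE)))))
  if (!is.finite(ll)) ll <- -1e10
  -ll
}

fit_glmm_gh <- function(formula, data, group, family,
                        quadrature_order = 20, n_restarts = 3, seed = 1L,
                        compute_se = TRUE) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (family == "zip") {
    if (any(y < 0))
      stop_invalid(paste0(
        "zero-inflated Poisson response must be a nonnegative integer; ",
        "negative differences present - preprocess with ",
        "response_differences(floor_at_zero = TRUE) or use the raw-difference ",
        "Gaussian route"))
    if (any(y != round(y))) stop_invalid("response must be integer counts")
  } else {
    if (!all(y %in% c(0, 1))) stop_invalid("binary response required")
  }
  grp <- factor(data[[group]])
  if (length(grp) != nrow(X))
    stop_invalid("missing values in model variables are not supported")
  if (nlevels(grp) < 2) stop_invalid("need at least 2 groups for a random intercept")
  group_idx <- as.integer(grp)
  gh <- pracma::gaussHermite(quadrature_order)

  glm_fam <- if (family == "zip") stats::poisson() else stats::binomial()
  start_glm <- suppressWarnings(stats::glm.fit(X, y, family = glm_fam))
  beta0 <- start_glm$coefficients
  beta0[!is.finite(beta0)] <- 0
  theta0 <- if (family == "zip") {
    p0_obs <- mean(y == 0)
    p0_fit <- mean(stats::dpois(0, exp(drop(X %*% beta0))))
    zi0 <- min(max((p0_obs - p0_fit) / max(1 - p0_fit, 1e-6), 0.02), 0.8)
    c(beta0, stats::qlogis(zi0), log(0.2))
  } else c(beta0, log(0.2))

  nll <- function(th) glmm_negloglik(th, y, X, group_idx, nlevels(grp), gh, family)
  best <- NULL
  starts <- with_seed(seed, {
    lapply(seq_len(n_restarts), function(r) {
      if (r == 1) theta0 else theta0 + rnorm(length(theta0), 0, 0.3)
    })
  })
  for (th in starts) {
    fit <- tryCatch(
      stats::optim(th, nll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  H <- if (compute_se)
    tryCatch(stats::optimHess(best$par, nll), error = function(e) NULL)
  else NULL
  vc <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  p <- ncol(X)
  beta <- setNames(best$par[seq_len(p)], colnames(X))
  se <- if (!is.null(vc) && all(diag(vc)[seq_len(p)] > 0))
    sqrt(diag(vc)[seq_len(p)]) else rep(NA_real_, p)
  zi_logit <- if (family == "zip") unname(best$par[p + 1]) else NA_real_
  sigma_b <- unname(exp(best$par[length(best$par)]))
  separation <- family == "binomial" && any(abs(beta) > 15)
  structure(list(
    beta = beta, se = setNames(se, colnames(X)),
    vcov = if (!is.null(vc)) vc[seq_len(p), seq_len(p), drop = FALSE] else NULL,
    zi_logit = zi_logit,
    zi_prob = if (family == "zip") stats::plogis(zi_logit) else NA_real_,
    sigma_b = sigma_b, loglik = -best$value,
    converged = best$convergence == 0 && is.finite(best$value),
    singular = sigma_b < 1e-4, separation = separation,
    n_obs = nrow(X), n_groups = nlevels(grp),
    quadrature_order = quadrature_order, family = family,
    formula = formula, group = group,
    xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
    term_assign = attr(X, "assign"),
    term_labels = attr(stats::terms(formula), "term.labels")
  ), class = "mixed_fit")
}

#' Zero-inflated Poisson mixed model (random subject intercept)
#'
#' Maximises the marginal likelihood of the mixture
#' `pi * 1{y = 0} + (1 - pi) * Poisson(y; exp(x'beta + b))` with
#' `b ~ N(0, sigma_b^2)` per group, the random intercept integrated out by
#' Gauss-Hermite quadrature and the parameters optimised by BFGS from a
#' Poisson-GLM start (with jittered restarts). The zero-inflation
#' probability `pi` is intercept-only on the logit scale.
#'
#' @param formula Fixed-effects formula (response on the left).
#' @param data Data frame.
#' @param group Name of the grouping column (the random intercept).
#' @param quadrature_order Number of Gauss-Hermite nodes.
#' @param n_restarts Optimiser restarts from jittered starts.
#' @param seed Seed for the restart jitter.
#' @param compute_se Compute the Hessian-based covariance of the fixed
#'   effects (skip in large simulation loops where only the likelihood or
#'   point estimates are needed).
#' @return An object of class `mixed_fit`: named fixed effects `beta` with
#'   `se` and `vcov`, `zi_prob`, `sigma_b`, `loglik`, `converged`,
#'   `singular`, bookkeeping fields.
#' @export
fit_zip_mixed <- function(formula, data, group = "subject_id",
                          quadrature_order = 20, n_restarts = 3, seed = 1L,
                          compute_se = TRUE) {
  fit_glmm_gh(formula, data, group, "zip", quadrature_order, n_restarts,
              seed, compute_se)
}

#' Logistic mixed model (random subject intercept)
#'
#' Bernoulli-logit counterpart of [fit_zip_mixed]. Complete separation is
#' detected heuristically (a fixed effect diverging beyond |15| on the logit
#' scale) and flagged in the `separation` field rather than raised as an
#' error, mirroring how pathological subset models manifest in practice.
#'
#' @inheritParams fit_zip_mixed
#' @return A `mixed_fit`.
#' @export
fit_logistic_mixed <- function(formula, data, group = "subject_id",
                               quadrature_order = 20, n_restarts = 3,
                               seed = 1L, compute_se = TRUE) {
  fit_glmm_gh(formula, data, group, "binomial", quadrature_order,
              n_restarts, seed, compute_se)
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf("<mixed_fit (%s): n=%d, groups=%d, logLik=%.3f%s%s>\n",
              x$family, x$n_obs, x$n_groups, x$loglik,
              if (x$singular) ", singular" else "",
              if (isTRUE(x$separation)) ", separation suspected" else ""))
  print(round(cbind(estimate = x$beta, se = x$se), 4))
  cat(sprintf("sigma_b = %.4f", x$sigma_b))
  if (x$family == "zip") cat(sprintf(", zi_prob = %.4f", x$zi_prob))
  cat("\n")
  invisible(x)
}

#' Likelihood-ratio test between nested mixed fits
#'
#' @param full,null Two `mixed_fit`s on the same data, the null's fixed
#'   terms a subset of the full's.
#' @return Data frame: chi2 (floored at 0), df, p.
#' @export
likelihood_ratio_test <- function(full, null) {
  if (!identical(full$family, null$family) || full$n_obs != null$n_obs)
    stop_invalid("models must share family and data")
  if (!all(names(null$beta) %in% names(full$beta)))
    stop_invalid("models are not nested (null terms not a subset of full)")
  df <- length(full$beta) - length(null$beta)
  chi2 <- max(0, 2 * (full$loglik - null$loglik))
  # identical fixed structures: a degenerate but legal comparison
  p <- if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  data.frame(chi2 = chi2, df = df, p = p)
}

#' Pairwise contrasts of a factor's levels
#'
#' All pairwise differences between the estimated level effects of one
#' fixed factor (treatment coding; the reference level's effect is 0), with
#' delta-method standard errors from the fit's covariance, normal z
#' statistics, and a multiplicity adjustment: Bonferroni (default) or the
#' studentized-range (Tukey) reference.
#'
#' @param fit A `mixed_fit`.
#' @param factor_name Name of the factor (must have entered the model).
#' @param method `"bonferroni"` or `"tukey"`.
#' @return Data frame: level_1, level_2, estimate, se, z, p_raw, p_adj,
#'   method.
#' @export
pairwise_contrasts <- function(fit, factor_name,
                               method = c("bonferroni", "tukey")) {
  method <- match.arg(method)
  levs <- fit$xlevels[[factor_name]]
  if (is.null(levs) || length(levs) < 2)
    stop_invalid("factor '%s' with >= 2 levels not found in fit", factor_name)
  coef_of <- function(l) {
    nm <- paste0(factor_name, l)
    if (nm %in% names(fit$beta)) fit$beta[[nm]] else 0
  }
  var_of <- function(l1, l2) {
    nms <- paste0(factor_name, c(l1, l2))
    present <- nms %in% names(fit$beta)
    if (is.null(fit$vcov)) return(NA_real_)
    idx <- match(nms[present], names(fit$beta))
    if (length(idx) == 1) fit$vcov[idx, idx]
    else fit$vcov[idx[1], idx[1]] + fit$vcov[idx[2], idx[2]] -
      2 * fit$vcov[idx[1], idx[2]]
  }
  pairs <- utils::combn(levs, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    l1 <- pairs[1, j]; l2 <- pairs[2, j]
    est <- coef_of(l1) - coef_of(l2)
    v <- var_of(l1, l2)
    se <- if (is.finite(v) && v >= 0) sqrt(v) else NA_real_
    z <- if (!is.na(se) && se > 0) est / se else if (est == 0) 0 else NA_real_
    p_raw <- if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z))
    p_adj <- if (is.na(p_raw)) NA_real_ else switch(
      method,
      bonferroni = min(1, m * p_raw),
      tukey = stats::ptukey(abs(z) * sqrt(2), length(levs), Inf,
                            lower.tail = FALSE))
    data.frame(level_1 = l1, level_2 = l2, estimate = est, se = se, z = z,
               p_raw = p_raw, p_adj = p_adj, method = method,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generalized variance inflation factors
#'
#' For each term of a fixed-effects design, `GVIF = det(R_t) det(R_-t) /
#' det(R)` on the correlation matrix of the non-intercept design columns;
#' for 1-df terms this is the classical `1 / (1 - R^2)`. The
#' df-adjusted `GVIF^(1/(2 df))` is also reported. Perfectly collinear
#' columns yield an infinite VIF.
#'
#' @param formula Fixed-effects formula (right-hand side is used).
#' @param data Data frame.
#' @return Data frame: term, df, gvif, gvif_adj.
#' @export
vif_terms <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  asgn <- attr(X, "assign")
  labels <- attr(stats::terms(formula), "term.labels")
  keep <- asgn != 0
  X <- X[, keep, drop = FALSE]; asgn <- asgn[keep]
  if (length(labels) < 2)
    stop_invalid("vif needs at least 2 predictor terms")
  R <- suppressWarnings(stats::cor(X))
  detR <- det(R)
  rows <- lapply(seq_along(labels), function(t) {
    cols <- which(asgn == t)
    df <- length(cols)
    gvif <- if (detR <= 1e-12) {
      Inf
    } else {
      det(R[cols, cols, drop = FALSE]) *
        det(R[-cols, -cols, drop = FALSE]) / detR
    }
    data.frame(term = labels[t], df = df, gvif = gvif,
               gvif_adj = gvif ^ (1 / (2 * df)), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
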