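# Simulated mixed-model data with known truth, bypassing the playback
# machinery, for estimator-level checks.
sim_zip_data <- function(n_subj = 9, n_per = 8, beta0 = 0.8, beta_x = 0.5,
                         sigma = 0.3, zi = 0.2, seed = 1) {
  with_seed(seed, {
    b <- rnorm(n_subj, 0, sigma)
    d <- data.frame(subject_id = rep(sprintf("S%02d", 1:n_subj), each = n_per),
                    x = rep(c(0, 1), length.out = n_subj * n_per))
    eta <- beta0 + beta_x * d$x + b[rep(1:n_subj, each = n_per)]
    y <- rpois(nrow(d), exp(eta))
    y[runif(nrow(d)) < zi] <- 0L
    d$y <- y
    d
  })
}

test_that("response differences and their bookkeeping", {
  d <- data.frame(subject_id = "S1", sex = "female", trial_order = 1:4,
                  receiver_context = "social", trigger_context = "high_social",
                  gazes_before = c(2, 3, 5, NA), gazes_after = c(5, 3, 2, 4),
                  sdb_before = 0:3, sdb_after = c(1, 1, 1, 1),
                  yawn_before = 0L, yawn_after = c(0L, 1L, 0L, 1L))
  r <- response_differences(d, floor_at_zero = FALSE)
  expect_equal(r$gaze_diff, c(3, 0, -3))
  expect_equal(nrow(attr(r, "rejected")), 1)
  r0 <- response_differences(d)
  expect_equal(r0$gaze_diff, c(3, 0, 0))
  expect_true(all(r0$sdb_diff >= 0))
  expect_equal(r0$yawn_response, c(0, 1, 0))
})

test_that("with no random effect or zero inflation the ZIP fit reduces to a Poisson GLM", {
  # The zi estimate is a boundary parameter: on samples with a chance excess
  # of zeros its MLE is legitimately positive, and the fixed effects then
  # differ from the plain-Poisson fit by O(zi). The clean reduction check
  # therefore uses a sample whose zero count does not exceed the Poisson
  # expectation (zi MLE collapses to the boundary).
  d <- sim_zip_data(n_subj = 10, n_per = 100, sigma = 0, zi = 0, seed = 9)
  expect_lte(sum(d$y == 0), sum(dpois(0, fitted(glm(y ~ x, poisson, d)))))
  fit <- fit_zip_mixed(y ~ x, d, quadrature_order = 20)
  glm_fit <- glm(y ~ x, poisson, d)
  expect_lt(max(abs(fit$beta - coef(glm_fit))), 1e-3)
  expect_lt(fit$zi_prob, 0.01)
  expect_lt(fit$sigma_b, 0.05)
  expect_true(fit$converged)
})

test_that("the ZIP likelihood itself reduces to an independent ZIP-GLM oracle", {
  skip_if_not_installed("glmmTMB")
  # zero-excess sample: the zi part is interior, so this checks the mixture
  # likelihood (not just the Poisson limb) against glmmTMB without a random
  # effect
  d <- sim_zip_data(n_subj = 10, n_per = 40, sigma = 0, zi = 0.2, seed = 1)
  fit <- fit_zip_mixed(y ~ x, d, quadrature_order = 20)
  expect_true(fit$singular || fit$sigma_b < 0.01)  # reduction condition holds
  orc <- glmmTMB::glmmTMB(y ~ x, ziformula = ~1, family = stats::poisson,
                          data = d)
  expect_lt(max(abs(fit$beta - glmmTMB::fixef(orc)$cond)), 1e-3)
  expect_equal(fit$zi_prob,
               stats::plogis(glmmTMB::fixef(orc)$zi[[1]]), tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(stats::logLik(orc)), tolerance = 1e-4)
})

test_that("with no random effect the logistic fit reduces to a logistic GLM", {
  d <- with_seed(6, {
    d <- data.frame(subject_id = rep(sprintf("S%d", 1:10), each = 40),
                    x = rnorm(400))
    d$y <- rbinom(400, 1, plogis(-0.3 + 0.8 * d$x))
    d
  })
  fit <- fit_logistic_mixed(y ~ x, d, quadrature_order = 20)
  glm_fit <- glm(y ~ x, binomial, d)
  expect_lt(max(abs(fit$beta - coef(glm_fit))), 1e-3)
  expect_false(fit$separation)
})

test_that("mixed fits agree with glmmTMB on a shared dataset", {
  skip_if_not_installed("glmmTMB")
  d <- sim_zip_data(seed = 8)
  fit <- fit_zip_mixed(y ~ x, d)
  tmb <- glmmTMB::glmmTMB(y ~ x + (1 | subject_id), ziformula = ~1,
                          family = stats::poisson, data = d)
  expect_equal(fit$loglik, as.numeric(stats::logLik(tmb)), tolerance = 1e-2)
  expect_lt(max(abs(fit$beta - glmmTMB::fixef(tmb)$cond)), 0.02)
})

test_that("doubling the quadrature order leaves the log-likelihood unchanged", {
  d <- sim_zip_data(seed = 10)
  f20 <- fit_zip_mixed(y ~ x, d, quadrature_order = 20)
  f40 <- fit_zip_mixed(y ~ x, d, quadrature_order = 40)
  expect_lt(abs(f20$loglik - f40$loglik), 1e-4)
  d$yb <- as.integer(d$y > 0)
  b20 <- fit_logistic_mixed(yb ~ x, d, quadrature_order = 20)
  b40 <- fit_logistic_mixed(yb ~ x, d, quadrature_order = 40)
  expect_lt(abs(b20$loglik - b40$loglik), 1e-4)
})

test_that("degenerate binary responses are flagged as separation", {
  d <- sim_zip_data(seed = 12)
  d$y0 <- 0L
  fit <- suppressWarnings(fit_logistic_mixed(y0 ~ x, d, n_restarts = 1))
  expect_true(fit$separation || fit$beta[["(Intercept)"]] < -10)
})

test_that("negative count responses point the user to the preprocessing flag", {
  d <- sim_zip_data(seed = 14)
  d$y[1] <- -2L
  expect_error(fit_zip_mixed(y ~ x, d), "floor_at_zero")
})

test_that("the LRT is zero for identical models and monotone in nesting", {
  d <- sim_zip_data(seed = 16)
  full <- fit_zip_mixed(y ~ x, d)
  null <- fit_zip_mixed(y ~ 1, d)
  lrt <- likelihood_ratio_test(full, null)
  expect_gte(lrt$chi2, 0)
  expect_equal(lrt$df, 1)
  expect_gte(full$loglik, null$loglik)   # likelihood monotone in nesting
  self <- likelihood_ratio_test(full, full)
  expect_equal(self$chi2, 0)
  expect_equal(self$p, 1)
  expect_error(likelihood_ratio_test(null, full), "nested")
  same <- likelihood_ratio_test(
    fit_zip_mixed(y ~ x, d), fit_zip_mixed(y ~ 1, d))
  expect_equal(same$p, pchisq(same$chi2, 1, lower.tail = FALSE))
})

test_that("pairwise contrasts cover all level pairs with adjusted p-values", {
  des <- paper_scale_design(seed = 31)
  trials <- response_differences(model_subset(
    generate_behavioral_dataset(des, seed = 2), 1))
  fit <- fit_zip_mixed(
    gaze_diff ~ sex + receiver_context + trigger_context + trial_order, trials)
  ct <- pairwise_contrasts(fit, "trigger_context")
  expect_equal(nrow(ct), 3)  # C(3,2)
  expect_true(all(ct$p_adj >= ct$p_raw - 1e-12, na.rm = TRUE))
  expect_true(all(ct$p_adj <= 1))
  tk <- pairwise_contrasts(fit, "trigger_context", method = "tukey")
  expect_true(all(tk$p_adj >= tk$p_raw - 1e-12, na.rm = TRUE))
  expect_error(pairwise_contrasts(fit, "no_such_factor"), "not found")
  # equal level estimates give z = 0 and adjusted p = 1
  fit2 <- fit
  fit2$beta[grep("trigger_context", names(fit2$beta))] <- 0
  ct2 <- pairwise_contrasts(fit2, "trigger_context")
  expect_equal(ct2$estimate[ct2$level_1 == "low_social" &
                              ct2$level_2 == "non_social"], 0)
})

test_that("VIFs are 1 for orthogonal designs and explode under collinearity", {
  d <- with_seed(21, data.frame(x1 = rep(c(-1, 1), 20), x2 = rep(c(-1, 1), each = 20),
                                x3 = rnorm(40)))
  d$x3 <- residuals(lm(x3 ~ x1 + x2, d))  # orthogonalised
  v <- vif_terms(~ x1 + x2 + x3, d)
  expect_equal(v$gvif, rep(1, 3), tolerance = 1e-10)
  d$x4 <- d$x1
  v2 <- vif_terms(~ x1 + x2 + x4, d)
  expect_true(any(!is.finite(v2$gvif) | v2$gvif > 1e6))
})

test_that("generalized VIFs match car::vif on the study's factor design", {
  skip_if_not_installed("car")
  des <- paper_scale_design(seed = 33)
  trials <- response_differences(model_subset(
    generate_behavioral_dataset(des, seed = 3), 1))
  form <- gaze_diff ~ sex + receiver_context + trigger_context + trial_order
  mine <- vif_terms(form, trials)
  lm_fit <- lm(form, trials)
  theirs <- car::vif(lm_fit)
  gv <- if (is.matrix(theirs)) theirs[, "GVIF"] else theirs
  expect_equal(mine$gvif, unname(gv[mine$term]), tolerance = 1e-6)
  # balanced design: all low, consistent with a well-conditioned model
  expect_true(all(mine$gvif_adj < 2.5))
})
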