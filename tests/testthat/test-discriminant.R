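test_that("well-separated classes are classified perfectly along the right axis", {
  tab <- with_seed(1, {
    X <- rbind(cbind(rnorm(15, 0, 0.3), rnorm(15, 0, 0.3)),
               cbind(rnorm(15, 10, 0.3), rnorm(15, 0, 0.3)))
    data.frame(feat1 = X[, 1], feat2 = X[, 2],
               context = rep(c("a", "b"), each = 15))
  })
  m <- fit_dfa(tab, c("feat1", "feat2"))
  pr <- predict(m, tab)
  expect_equal(as.character(pr$class), tab$context)
  # discriminant axis points essentially along feat1
  a <- m$scaling[, 1] / sqrt(sum(m$scaling[, 1]^2))
  expect_gt(abs(a[1]), 0.95)
  lo <- classify_loocv(tab, c("feat1", "feat2"))
  expect_equal(lo$total_prop, 1.0)
})

test_that("Mahalanobis classification matches the posterior argmax", {
  tab <- gaussian_feature_table(n_per_class = 12, sep = 2, seed = 3)
  m <- fit_dfa(tab, paste0("feat", 1:4))
  new <- with_seed(9, as.data.frame(matrix(rnorm(100 * 4, 1, 2), 100, 4,
                                           dimnames = list(NULL, paste0("feat", 1:4)))))
  pr <- predict(m, new)
  expect_equal(as.integer(pr$class), apply(pr$posterior, 1, which.max))
  expect_equal(as.integer(pr$class), apply(pr$d2, 1, which.min))  # uniform priors
})

test_that("fit_dfa agrees with an established LDA implementation", {
  skip_if_not_installed("MASS")
  tab <- gaussian_feature_table(n_per_class = 15, sep = 1.5, seed = 7)
  feats <- paste0("feat", 1:4)
  m <- fit_dfa(tab, feats)
  ml <- MASS::lda(tab[feats], grouping = factor(tab$context))
  pl <- predict(ml)
  pm <- predict(m, tab)
  expect_equal(as.character(pm$class), as.character(pl$class))
  # discriminant scores agree up to sign per axis
  for (j in 1:2)
    expect_gt(abs(cor(pm$scores[, j], pl$x[, j])), 0.999)
})

test_that("LOOCV equals a naive refit-per-fold oracle", {
  tab <- gaussian_feature_table(n_per_class = 10, sep = 1, seed = 11)
  feats <- paste0("feat", 1:4)
  lo <- classify_loocv(tab, feats)
  naive <- vapply(seq_len(nrow(tab)), function(i) {
    m <- fit_dfa(tab[-i, ], feats)
    as.character(predict(m, tab[i, , drop = FALSE])$class)
  }, character(1))
  expect_equal(lo$predictions$predicted, naive)
  # confusion-matrix accounting
  expect_equal(sum(lo$confusion), nrow(tab))
  expect_equal(unname(rowSums(lo$confusion)),
               unname(as.vector(table(tab$context))))
  expect_equal(lo$total_prop, sum(diag(lo$confusion)) / nrow(tab))
})

test_that("folds that would empty a class are flagged and excluded", {
  tab <- gaussian_feature_table(n_per_class = 10, sep = 2, seed = 13)[1:22, ]
  # class "c" has only 2 rows: both of its folds must be flagged
  lo <- classify_loocv(tab, paste0("feat", 1:4))
  expect_equal(lo$n_flagged, 2)
  expect_equal(sum(lo$confusion), 20)
})

test_that("permuted labels drive accuracy to chance", {
  accs <- vapply(1:30, function(r) {
    tab <- gaussian_feature_table(n_per_class = 10, sep = 2, seed = 17)
    tab$context <- with_seed(100 + r, sample(tab$context))
    classify_loocv(tab, paste0("feat", 1:4))$total_prop
  }, numeric(1))
  # mean accuracy within 3 SE of the pooled chance 1/3
  expect_lt(abs(mean(accs) - 1 / 3), 3 * sqrt(var(accs) / 30) + 0.02)
  # and eigenvalues collapse relative to the true-label fit
  tab <- gaussian_feature_table(n_per_class = 10, sep = 2, seed = 17)
  ev_true <- fit_dfa(tab, paste0("feat", 1:4))$eigenvalues[1]
  tab$context <- with_seed(5, sample(tab$context))
  ev_perm <- fit_dfa(tab, paste0("feat", 1:4))$eigenvalues[1]
  expect_lt(ev_perm, ev_true / 5)
})

test_that("chance probabilities are class proportions", {
  labels <- rep(c("high_social", "low_social", "non_social"), c(41, 26, 21))
  ch <- chance_probabilities(labels)
  expect_equal(ch$class_probs[match("low_social", ch$classes)], 26 / 88)
  expect_equal(round(ch$class_probs[match("low_social", ch$classes)], 3), 0.295)
  expect_equal(ch$pooled, 1 / 3)
  expect_equal(sum(ch$class_probs), 1)
  ch2 <- chance_probabilities(rep(c("a", "b", "c"), each = 10))
  expect_equal(ch2$class_probs, rep(1 / 3, 3))
})

test_that("binomial tail tests match closed forms and stats::binom.test", {
  expect_equal(binomial_test(2, 2, 0.5, "greater")$p_value, 0.25)
  expect_equal(binomial_test(0, 7, 0.3, "greater")$p_value, 1.0)
  # brute-force tail summation oracle across a grid, 1e-12 relative
  for (n in c(10, 88, 500)) {
    for (p0 in c(0.2, 1 / 3, 0.7)) {
      for (k in unique(c(0, 1, round(n * p0), n - 1, n))) {
        brute <- sum(vapply(k:n, function(j) choose(n, j) * p0^j *
                              (1 - p0)^(n - j), numeric(1)))
        mine <- binomial_test(k, n, p0, "greater")$p_value
        expect_equal(mine, min(1, brute), tolerance = 1e-12)
        expect_equal(mine,
                     stats::binom.test(k, n, p0, "greater")$p.value,
                     tolerance = 1e-12)
        expect_equal(binomial_test(k, n, p0, "two_sided")$p_value,
                     stats::binom.test(k, n, p0, "two.sided")$p.value,
                     tolerance = 1e-9)
      }
    }
  }
  expect_error(binomial_test(3, 2, 0.5), "k must be")
  expect_error(binomial_test(1, 2, 0), "p0")
})

test_that("classification assessment combines per-class and pooled tests", {
  tab <- gaussian_feature_table(n_per_class = 10, sep = 4, seed = 19)
  lo <- classify_loocv(tab, paste0("feat", 1:4))
  expect_equal(lo$total_prop, 1)  # fully separable
  as <- assess_classification(lo)
  expect_equal(nrow(as), 4)
  # all correct: per-class p = p0 ^ n
  for (i in 1:3) expect_equal(as$p_value[i], as$p0[i] ^ as$n[i])
  # below-expectation class gives a greater-tail p above 0.5
  lo_bad <- lo
  lo_bad$confusion[1, ] <- c(1, 5, 4)
  as_bad <- assess_classification(lo_bad)
  expect_gt(as_bad$p_value[1], 0.5)
})

test_that("contribution table is long-format, bounded, NA-safe", {
  tab <- gaussian_feature_table(n_per_class = 20, sep = 2, seed = 23)
  feats <- paste0("feat", 1:4)
  m <- fit_dfa(tab, feats)
  sc <- predict(m, tab)$scores
  tab$ld1_copy <- sc[, 1]
  contrib <- contribution_matrix(tab, c(feats, "ld1_copy"), m)
  expect_equal(nrow(contrib), 5 * 2)  # feature x axis
  expect_true(all(abs(contrib$r) <= 1, na.rm = TRUE))
  expect_equal(contrib$r[contrib$feature == "ld1_copy" &
                           contrib$axis == "LD1"], 1)
  tab$flat <- 1
  expect_warning(c2 <- contribution_matrix(tab, c("feat1", "flat"), m),
                 "zero-variance")
  expect_true(all(is.na(c2$r[c2$feature == "flat"])))
})
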