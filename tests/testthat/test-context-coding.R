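test_that("coefficient-of-variation formulas match hand-computed values", {
  expect_equal(cv_within(c(10, 10, 10)), 0)
  # 100 * (2/10) * (1 + 1/12)
  expect_equal(cv_within(c(8, 10, 12)), 100 * (2 / 10) * (1 + 1 / 12))
  expect_equal(cv_within(c(8, 10, 12)), 21.66667, tolerance = 1e-6)
  expect_equal(cv_between(c(8, 10, 12)), 20)
  expect_equal(cv_between(rep(4, 6)), 0)
  # large-n limit: correction factor -> 1
  x <- rep(c(8, 10, 12), 400)
  expect_equal(cv_within(x), cv_between(x), tolerance = 1e-3)
  expect_error(cv_within(c(-5, 5)), class = "callcontext_undefined_cv")
  expect_error(cv_within(7), "at least 2")
})

test_that("PCC separates within- from between-context variation", {
  # three identical groups: between-variation equals pooled CV, but the
  # small-sample correction inflates CVw -> PCC < 1
  v <- rep(c(8, 10, 12), 3)
  g <- rep(c("a", "b", "c"), each = 3)
  row <- pcc_index(v, g)
  expect_equal(row$cvb, cv_between(v))
  expect_equal(row$mean_cvw, cv_within(c(8, 10, 12)))
  expect_equal(row$pcc, row$cvb / row$mean_cvw)
  expect_lt(row$pcc, 1)
  # groups far apart with tiny within-spread -> PCC >> 1
  v2 <- c(1, 1.01, 10, 10.1, 100, 101)
  g2 <- rep(c("a", "b", "c"), each = 2)
  expect_gt(pcc_index(v2, g2)$pcc, 10)
  # all values identical -> 0/0 -> flagged undefined
  row3 <- pcc_index(rep(5, 9), g)
  expect_false(row3$defined)
  expect_true(is.na(row3$pcc))
})

test_that("PCC is invariant to positive rescaling", {
  with_seed(2, {
    v <- rlnorm(30, 2, 0.4)
    g <- rep(c("a", "b", "c"), 10)
    expect_equal(pcc_index(v * 17.3, g)$pcc, pcc_index(v, g)$pcc)
  })
})

test_that("under a pure-noise null the median PCC sits below 1", {
  with_seed(99, {
    pccs <- replicate(500, {
      v <- rlnorm(24, 1, 0.3)
      g <- rep(c("a", "b", "c"), each = 8)
      pcc_index(v, g)$pcc
    })
  })
  expect_lt(median(pccs), 1)
})

test_that("balancing caps caller-context cells and is seed-stable", {
  tab <- data.frame(
    call_id = sprintf("c%02d", 1:14),
    caller_id = c(rep("M1", 5), rep("M2", 2), rep("M1", 3), rep("M2", 4)),
    context = c(rep("a", 7), rep("b", 7)),
    feat1 = rnorm(14), stringsAsFactors = FALSE)
  b <- balance_by_caller(tab, max_per = 2, seed = 3)
  expect_true(all(table(b$caller_id, b$context) <= 2))
  expect_equal(nrow(b) + nrow(attr(b, "removed")), nrow(tab))
  expect_identical(balance_by_caller(tab, max_per = 2, seed = 3)$call_id,
                   b$call_id)
  # cap above all cell sizes: identity
  expect_equal(nrow(balance_by_caller(tab, max_per = 10, seed = 1)), 14)
})

test_that("three-step selection keeps one representative per redundant set", {
  with_seed(2, {
    n <- 60
    g <- rep(c("a", "b", "c"), each = n / 3)
    base <- rnorm(n, 10, 1) + 1 * (g == "b") - 1 * (g == "c")
    tab <- data.frame(
      context = g,
      sig_median = base,                       # informative
      sig_mean = base + rnorm(n, 0, 0.05),     # near-duplicate of sig_median
      noise1 = rlnorm(n, 2, 0.5),              # heavy-tailed noise
      indep = rnorm(n, 20, 2) + 3 * (g == "a") # second informative feature
    )
  })
  rep_df <- select_features(tab, features = c("sig_median", "sig_mean",
                                              "noise1", "indep"))
  expect_s3_class(rep_df, "selection_report")
  # audit trail covers every input feature exactly once
  expect_setequal(rep_df$feature, c("sig_median", "sig_mean", "noise1", "indep"))
  expect_true(all(nzchar(rep_df$rationale)))
  # the duplicated pair collapses to its median-type member
  expect_true(rep_df$retained[rep_df$feature == "sig_median"])
  expect_false(rep_df$retained[rep_df$feature == "sig_mean"])
  expect_match(rep_df$rationale[rep_df$feature == "sig_mean"], "redundant")
  # retained implies passing every step
  ok <- rep_df$retained
  expect_true(all(rep_df$passed_pcc[ok] & rep_df$passed_normality[ok] &
                    rep_df$is_representative[ok]))
})

test_that("pure-noise features pass the screen only at the null rate", {
  # Oracle (direct simulation of PCC >= 1 together with a passing pooled
  # Shapiro-Wilk for i.i.d. normal features, 3 contexts x 8 calls): the
  # null retention probability is ~= 0.30, because the null PCC
  # distribution straddles 1. The empirical rate over 200 datasets must
  # match that within Monte-Carlo error, and the median null PCC must sit
  # below 1 (the small-sample correction inflates CVw).
  hits <- 0L
  for (r in 1:200) {
    with_seed(1000 + r, {
      g <- rep(c("a", "b", "c"), each = 8)
      tab <- data.frame(context = g, f1 = rnorm(24, 10, 1),
                        f2 = rnorm(24, 10, 1), f3 = rnorm(24, 10, 1))
    })
    rep_df <- select_features(tab)
    hits <- hits + rep_df$retained[rep_df$feature == "f1"]
  }
  expect_gt(hits / 200, 0.15)
  expect_lt(hits / 200, 0.45)
})

test_that("an all-noise panel yields an explicit empty selection", {
  with_seed(7, {
    g <- rep(c("a", "b"), each = 10)
    # constant features: PCC undefined -> nothing survives
    tab <- data.frame(context = g, f1 = rep(2, 20), f2 = rep(3, 20),
                      f3 = rep(4, 20))
  })
  rep_df <- select_features(tab)
  expect_length(attr(rep_df, "retained"), 0)
  expect_true(all(!rep_df$retained))
})
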