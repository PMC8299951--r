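# ROC/AUC, DeLong comparisons, Youden operating points, normality screen,
# univariate logistic AUC and ICC.

test_that("AUC equals exhaustive pair counting over all short orderings", {
  base_scores <- c(0.31, 0.12, 0.77, 0.54, 0.92, 0.05, 0.68, 0.41)
  tied_scores <- c(0.3, 0.3, 0.7, 0.3, 0.7, 0.1, 0.7, 0.4)
  for (n in 2:8) {
    for (code in 1:(2^n - 2)) {
      labs <- ifelse(bitwAnd(code, 2^(seq_len(n) - 1)) > 0,
                     "malignant", "benign")
      for (sc in list(base_scores[1:n], tied_scores[1:n])) {
        expect_equal(auc_delong(sc, labs)$auc, oracle_auc(sc, labs),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("DeLong intervals behave at the extremes and under the null", {
  labs <- rep(c("benign", "malignant"), each = 20)
  perfect <- c(stats::runif(20, 0, 0.4), stats::runif(20, 0.6, 1))
  r <- auc_delong(perfect, labs)
  expect_equal(r$auc, 1)
  expect_equal(r$se, 0)
  expect_equal(r$ci, c(1, 1))

  null_scores <- withr::with_seed(20, stats::rnorm(2000))
  null_labs <- rep(c("benign", "malignant"), 1000)
  a <- auc_delong(null_scores, null_labs)$auc
  expect_gte(a, 0.47)
  expect_lte(a, 0.53)

  expect_error(auc_delong(1:5, rep("benign", 5)), "class")
})

test_that("the paired DeLong test is symmetric with sensible edge cases", {
  labs <- rep(c("benign", "malignant"), each = 20)
  set.seed(31)
  a <- stats::rnorm(40); b <- stats::rnorm(40)
  expect_equal(delong_test(a, a, labs), 1)
  expect_equal(delong_test(a, b, labs), delong_test(b, a, labs))

  perfect <- c(rep(0, 20), rep(1, 20))
  expect_lt(delong_test(perfect, 1 - perfect, labs), 0.001)
  expect_error(delong_test(a, b[1:20], labs), "length")
})

test_that("Youden operating points match an exhaustive threshold scan", {
  labs <- c("benign", "benign", "malignant", "malignant")
  m <- youden_metrics(c(0.1, 0.2, 0.8, 0.9), labs)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$accuracy, 1)

  # degenerate: all scores equal -> everything called positive
  md <- youden_metrics(rep(0.5, 4), labs)
  expect_equal(md$sensitivity, 1)
  expect_equal(md$specificity, 0)

  # six-score toy against a brute-force scan over all midpoints
  scores <- c(0.15, 0.4, 0.45, 0.6, 0.7, 0.9)
  labs6 <- c("benign", "benign", "malignant", "benign", "malignant",
             "malignant")
  pos <- labs6 == "malignant"
  cand <- c(min(scores) - 1,
            (sort(unique(scores))[-1] + rev(rev(sort(unique(scores)))[-1])) / 2)
  best <- -Inf; exp_sens <- NA; exp_spec <- NA
  for (thr in cand) {
    sens <- mean(scores[pos] > thr); spec <- mean(scores[!pos] <= thr)
    if (sens + spec - 1 > best) {
      best <- sens + spec - 1; exp_sens <- sens; exp_spec <- spec
    }
  }
  m6 <- youden_metrics(scores, labs6)
  expect_equal(m6$sensitivity, exp_sens)
  expect_equal(m6$specificity, exp_spec)

  # a supplied threshold is honored (validation-cohort pathway)
  mt <- youden_metrics(scores, labs6, threshold = 0.5)
  expect_equal(mt$threshold, 0.5)
  expect_equal(mt$sensitivity, mean(scores[pos] > 0.5))
})

test_that("the normality screen separates normal from uniform samples", {
  x_norm <- withr::with_seed(40, stats::rnorm(500))
  x_unif <- withr::with_seed(41, stats::runif(500))
  expect_identical(ks_normality(x_norm)$mode, "mean±SD")
  expect_identical(ks_normality(x_unif)$mode, "median±IQR")
  expect_identical(ks_normality(rep(3, 10))$mode, "median±IQR")
  expect_error(ks_normality(c(1, 2, 3)), "4")
})

test_that("univariate logistic AUC absorbs the sign of the association", {
  y <- rep(c("benign", "malignant"), each = 50)
  x <- as.numeric(y == "malignant")
  expect_equal(univariate_auc(x, y)$auc, 1)
  expect_equal(univariate_auc(-x, y)$auc, 1)

  x_noise <- withr::with_seed(50, stats::rnorm(1000))
  y_big <- rep(c("benign", "malignant"), 500)
  a <- univariate_auc(x_noise, y_big)$auc
  expect_gte(a, 0.46)
  expect_lte(a, 0.54)
})

test_that("ICC(2,1) matches hand ANOVA and is reader-symmetric", {
  expect_equal(icc_agreement(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(icc_agreement(c(1, 2, 3), c(2, 3, 4)), 2 / 3, tolerance = 1e-12)
  a <- withr::with_seed(60, stats::rnorm(50))
  b <- withr::with_seed(61, sample(a))
  expect_lt(abs(icc_agreement(a, b)), 0.35)
  x <- withr::with_seed(62, stats::rnorm(30))
  y <- x + withr::with_seed(63, stats::rnorm(30, 0, 0.3))
  expect_equal(icc_agreement(x, y), icc_agreement(y, x))
  expect_error(icc_agreement(1:2, 1:2), "3")
})
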