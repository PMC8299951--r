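# Prefiltering, LASSO selection, DT/SVM fitting and score prediction.

make_toy_table <- function(n = 200, p = 20, seed = 1, planted = TRUE) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p)
    colnames(X) <- sprintf("f%02d", seq_len(p))
    y <- rep(c("benign", "malignant"), length.out = n)
    if (planted) X[, 1] <- (y == "malignant") + stats::rnorm(n, 0, 0.1)
    list(X = X, y = y)
  })
}

test_that("the correlation prefilter drops later duplicates and constants", {
  tt <- make_toy_table(p = 6, planted = FALSE)
  X <- tt$X
  X[, 3] <- X[, 2]            # duplicate
  X[, 5] <- -X[, 4]           # negation: |r| = 1
  X[, 6] <- 7                 # constant
  pf <- prefilter_correlated(X)
  expect_true("f02" %in% pf$kept)
  expect_true("f03" %in% pf$removed_correlated)
  expect_true("f04" %in% pf$kept)
  expect_true("f05" %in% pf$removed_correlated)
  expect_identical(pf$removed_constant, "f06")

  # independent noise columns all survive
  pf2 <- prefilter_correlated(make_toy_table(planted = FALSE)$X)
  expect_length(pf2$kept, 20)

  # row permutation leaves the decision unchanged
  perm <- sample(nrow(X))
  pf3 <- prefilter_correlated(X[perm, ])
  expect_identical(pf$kept, pf3$kept)
})

test_that("LASSO finds a planted feature among noise", {
  tt <- make_toy_table(seed = 5)
  sel <- lasso_select(tt$X, tt$y, seed = 9)
  expect_true("f01" %in% sel$selected)
  expect_false(sel$empty)
  expect_true(all(names(sel$coefficients) %in% colnames(tt$X)))
  expect_error(lasso_select(tt$X, rep("benign", nrow(tt$X))), "class")
})

test_that("classifiers separate a separable toy set and are reproducible", {
  tt <- make_toy_table(seed = 2, p = 2)
  for (kind in c("dt", "svm")) {
    m <- fit_classifier(kind, tt$X, tt$y, seed = 3)
    expect_equal(auc_delong(m$cv_scores, tt$y)$auc, 1)
    m2 <- fit_classifier(kind, tt$X, tt$y, seed = 3)
    expect_identical(m$cv_scores, m2$cv_scores)
    expect_identical(m$hyper, m2$hyper)
    expect_identical(m$fold_id, m2$fold_id)
    # purity of prediction
    s1 <- predict_scores(m, tt$X)
    s2 <- predict_scores(m, tt$X)
    expect_identical(s1, s2)
  }
})

test_that("shuffled labels yield chance-level cross-validated AUC", {
  tt <- make_toy_table(seed = 7, planted = FALSE)
  y_shuffled <- withr::with_seed(8, sample(tt$y))
  for (kind in c("dt", "svm")) {
    m <- fit_classifier(kind, tt$X[, 1:5], y_shuffled, seed = 11)
    a <- auc_delong(m$cv_scores, y_shuffled)$auc
    expect_gte(a, 0.35)
    expect_lte(a, 0.65)
  }
})

test_that("decision-tree scores are leaf probabilities and SVM scores flip correctly", {
  tt <- make_toy_table(seed = 4, p = 3)
  dt <- fit_classifier("dt", tt$X, tt$y, seed = 6)
  sc <- predict_scores(dt, tt$X)
  expect_true(all(sc >= 0 & sc <= 1))
  # a separable toy tree has pure leaves
  expect_true(all(sc %in% c(0, 1)))

  svm <- fit_classifier("svm", tt$X, tt$y, seed = 6)
  sv <- predict_scores(svm, tt$X)
  # orientation contract: malignant cases score higher
  expect_gt(mean(sv[tt$y == "malignant"]), mean(sv[tt$y == "benign"]))

  expect_error(predict_scores(svm, tt$X[, 2:3]), "schema")
})

test_that("stratified folds are balanced, seeded, and guard degenerate splits", {
  y <- rep(c("benign", "malignant"), c(40, 60))
  f <- make_folds(y, 10, seed = 1)
  expect_identical(f, make_folds(y, 10, seed = 1))
  for (k in 1:10) {
    expect_setequal(unique(y[f == k]), c("benign", "malignant"))
  }
  expect_equal(unname(table(f[y == "benign"])), rep(4L, 10),
               ignore_attr = TRUE)
  expect_error(make_folds(rep(c("benign", "malignant"), c(5, 95)), 10),
               "stratification")
})

test_that("empty selections degrade to chance-level constant scores", {
  # a null model (no selected features) is represented downstream by
  # constant scores, which score AUC 0.5
  y <- rep(c("benign", "malignant"), each = 10)
  expect_equal(auc_delong(rep(0, 20), y)$auc, 0.5)
})
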