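# Histogram, GLCM, GRLM and wavelet feature extraction.

test_that("histogram moments match direct formulas and conventions", {
  h <- histogram_features(c(2, 4, 6))
  expect_equal(unname(h["hist_mean"]), 4)
  expect_equal(unname(h["hist_variance"]), 8 / 3)
  expect_equal(unname(h["hist_skewness"]), 0)

  h2 <- histogram_features(c(0, 255))
  expect_equal(unname(h2["hist_mean"]), 127.5)

  hc <- histogram_features(rep(7, 10))
  expect_equal(unname(hc), c(7, 0, 0, 0))

  expect_true(all(is.na(histogram_features(numeric(0)))))
})

test_that("co-occurrence matrices match pair enumeration on worked examples", {
  img <- rbind(c(0, 0), c(1, 1))
  msk <- matrix(TRUE, 2, 2)

  P0 <- glcm(img, msk, 0, 1, levels = 2)
  expect_equal(P0[1, 1], 0.5)
  expect_equal(P0[2, 2], 0.5)
  expect_equal(glcm_stats(P0)[["contrast"]], 0)

  P90 <- glcm(img, msk, 90, 1, levels = 2)
  expect_equal(P90[1, 2], 0.5)
  expect_equal(P90[2, 1], 0.5)
  s90 <- glcm_stats(P90)
  expect_equal(s90[["contrast"]], 1)
  expect_equal(s90[["dissimilarity"]], 1)
  expect_equal(s90[["homogeneity"]], 0.5)
})

test_that("co-occurrence matrices are symmetric probability distributions", {
  set.seed(11)
  for (rep in 1:10) {
    img <- matrix(sample(0:7, 100, replace = TRUE), 10, 10)
    msk <- matrix(stats::runif(100) < 0.8, 10, 10)
    for (a in c(0, 45, 90, 135)) {
      P <- glcm(img, msk, a, sample(1:4, 1), levels = 8)
      if (is.null(P)) next
      expect_equal(sum(P), 1, tolerance = 1e-12)
      expect_equal(unclass(P), t(unclass(P)), tolerance = 1e-15,
                   ignore_attr = TRUE)
      expect_true(all(P >= 0))
    }
  }
})

test_that("GLCM statistics hit their closed forms on degenerate matrices", {
  L <- 8L
  delta <- matrix(0, L, L); delta[3, 3] <- 1
  class(delta) <- c("cooc_matrix", class(delta))
  s <- glcm_stats(delta)
  expect_equal(s[["energy"]], 1)
  expect_equal(s[["entropy"]], 0)
  expect_equal(s[["max_probability"]], 1)
  expect_equal(s[["contrast"]], 0)

  unif <- matrix(1 / L^2, L, L)
  su <- glcm_stats(unif)
  expect_equal(su[["energy"]], 1 / L^2)
  expect_equal(su[["entropy"]], 2 * log(L))
})

test_that("GLCM block enumerates 380 canonically named values", {
  set.seed(3)
  img <- matrix(sample(0:31, 400, replace = TRUE), 20, 20)
  msk <- matrix(TRUE, 20, 20)
  blk <- glcm_block(img, msk, levels = 32)
  expect_length(blk, 380)
  expect_true(!anyNA(blk))
  expect_identical(names(blk),
                   feature_schema()[5:(4 + 380)])
  # contrast is linear in P, so the angle-averaged-matrix value equals the
  # mean of the four directional values at each distance
  for (d in 1:4) {
    dirs <- blk[sprintf("glcm_contrast_a%d_d%d", c(0, 45, 90, 135), d)]
    expect_equal(unname(blk[sprintf("glcm_contrast_amean_d%d", d)]),
                 mean(dirs), tolerance = 1e-12)
  }
})

test_that("run-length matrices match run enumeration on worked examples", {
  R <- grlm(matrix(c(0, 0, 1), 1, 3), matrix(TRUE, 1, 3), 0, levels = 2)
  expect_equal(R[1, 2], 1L)  # gray 0, length 2
  expect_equal(R[2, 1], 1L)  # gray 1, length 1
  s <- grlm_stats(R)
  expect_equal(s[["sre"]], 0.625)
  expect_equal(s[["rln"]], 1)

  # constant 4x4 region, horizontal: 4 runs of length 4
  Rc <- grlm(matrix(5L, 4, 4), matrix(TRUE, 4, 4), 0, levels = 8)
  expect_equal(sum(Rc), 4L)
  expect_equal(which(colSums(Rc) > 0), 4L)

  # all runs length 1 -> SRE = LRE = 1
  img <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  s1 <- grlm_stats(grlm(img, matrix(TRUE, 3, 3), 0, levels = 2))
  expect_equal(s1[["sre"]], 1)
  expect_equal(s1[["lre"]], 1)
})

test_that("runs cover every region pixel exactly once along their angle", {
  set.seed(7)
  for (rep in 1:5) {
    img <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
    msk <- matrix(stats::runif(64) < 0.7, 8, 8)
    if (!any(msk)) next
    for (a in c(0, 45, 90, 135)) {
      R <- grlm(img, msk, a, levels = 4)
      nz <- which(R > 0)
      lens <- (nz - 1) %/% nrow(R) + 1
      expect_equal(sum(R[nz] * lens), sum(msk))
    }
  }
})

test_that("wavelet features annihilate constants and count 13 per family", {
  patch <- matrix(7, 32, 32)
  msk <- matrix(TRUE, 32, 32)
  for (w in c("haar", "db2", "sym4")) {
    f <- dwt_features(patch, msk, w)
    expect_length(f, 13)
    expect_lt(max(abs(f[1:12])), 1e-8)
    # orthonormal low-pass doubles the constant per 2D level: 4 levels -> 2^4
    expect_equal(unname(f[13]), 7 * 16, tolerance = 1e-8)
  }
  expect_length(
    unlist(lapply(c("haar", "db2", "sym4"),
                  function(w) dwt_features(patch, msk, w))), 39)
})

test_that("the canonical schema has 467 uniquely named entries per block", {
  schema <- feature_schema()
  expect_length(schema, 467)
  expect_false(anyDuplicated(schema) > 0)
  expect_length(grep("^hist_", schema), 4)
  expect_length(grep("^glcm_", schema), 380)
  expect_length(grep("^grlm_", schema), 44)
  expect_length(grep("^dwt_", schema), 39)
  for (w in c("haar", "db2", "sym4")) {
    expect_length(grep(paste0("^dwt_", w, "_"), schema), 13)
  }
})

test_that("feature extraction is pure, translation invariant, and flags empty zones", {
  set.seed(21)
  img <- matrix(sample(0:255, 48 * 48, replace = TRUE), 48, 48)
  msk <- matrix(FALSE, 48, 48)
  msk[5:20, 6:22] <- TRUE
  f1 <- extract_features(img, msk)
  f2 <- extract_features(img, msk)
  expect_identical(f1, f2)
  expect_length(f1, 467)
  expect_identical(names(f1), feature_schema())

  # translate image + mask together: all features unchanged
  img_t <- matrix(0L, 48, 48); msk_t <- matrix(FALSE, 48, 48)
  img_t[11:48, 13:48] <- img[1:38, 1:36]
  msk_t[11:48, 13:48] <- msk[1:38, 1:36]
  f3 <- extract_features(img_t, msk_t)
  expect_equal(unname(f1), unname(f3), tolerance = 1e-12)

  fe <- extract_features(img, msk & FALSE)
  expect_true(all(is.na(fe)))
  expect_true(attr(fe, "missing"))
})
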