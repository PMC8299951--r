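# Subtraction, ROI normalization/quantization, spatial FCM and refinement.

test_that("subtraction is exact pixel arithmetic over the 8 phases", {
  pre <- matrix(100, 4, 4)
  post <- array(100, dim = c(4, 4, 8))
  sub <- subtract_phases(list(pre = pre, post = post))
  expect_equal(max(abs(sub)), 0)

  post[2, 3, 4] <- 150
  sub2 <- subtract_phases(list(pre = pre, post = post))
  expect_equal(sub2[2, 3, 4], 50)

  expect_error(subtract_phases(list(pre = pre, post = post[, , 1:7])), "8")

  # noiseless synthetic study: enhancement confined to the lesion
  sc <- make_noiseless_study(seed = 6)
  s4 <- subtract_phases(sc$study)[, , 4]
  expect_equal(max(abs(s4[!sc$mask])), 0, tolerance = 1e-9)
  expect_gt(min(s4[sc$mask]), 0)
})

test_that("normalization clips at mu +/- 3 sigma and quantizes half-up", {
  set.seed(2)
  img <- matrix(stats::rnorm(40 * 40, 100, 20), 40, 40)
  # probe pixels excluded from the ROI statistics but inside the quantized
  # bounding box, so mu and sigma are unaffected by their values
  roi <- matrix(TRUE, 40, 40)
  roi[1, 1:3] <- FALSE
  roi[1, 4] <- TRUE; roi[40, 40] <- TRUE  # bbox spans the full image
  mu <- mean(img[roi]); sg <- stats::sd(img[roi])
  img[1, 1] <- mu - 3 * sg
  img[1, 2] <- mu + 4 * sg   # beyond the window: clipped to 255
  img[1, 3] <- mu
  q2 <- normalize_quantize(img, roi)
  expect_equal(q2$mu, mu)
  expect_equal(q2$patch[1, 1], 0L)
  expect_equal(q2$patch[1, 2], 255L)
  expect_equal(q2$patch[1, 3], 128L)  # 127.5 rounds half-up

  # brute-force per-pixel mapping oracle on a uniform ramp
  ramp <- matrix(0:599, 20, 30)
  qr <- normalize_quantize(ramp, matrix(TRUE, 20, 30))
  lo <- qr$mu - 3 * qr$sigma
  oracle <- floor((pmin(pmax(ramp, lo), qr$mu + 3 * qr$sigma) - lo) /
                    (6 * qr$sigma) * 255 + 0.5)
  expect_equal(as.numeric(qr$patch), as.numeric(oracle))
  expect_true(all(qr$patch >= 0 & qr$patch <= 255))

  expect_error(normalize_quantize(img, matrix(FALSE, 40, 40)), "16")
  expect_error(normalize_quantize(matrix(5, 10, 10), matrix(TRUE, 10, 10)),
               "degenerate")
})

test_that("re-quantizing a quantized patch stays within 8 bits", {
  set.seed(4)
  img <- matrix(stats::rnorm(30 * 30, 50, 15), 30, 30)
  q <- normalize_quantize(img, matrix(TRUE, 30, 30))
  q2 <- normalize_quantize(q$patch + 0.0, matrix(TRUE, nrow(q$patch),
                                                 ncol(q$patch)))
  expect_true(all(q2$patch >= 0 & q2$patch <= 255))
})

test_that("spatial FCM recovers a two-level disk against the Otsu oracle", {
  nr <- 48
  disk <- outer(1:nr, 1:nr, function(r, c) (r - 24)^2 + (c - 24)^2 <= 14^2)
  img <- matrix(30, nr, nr)
  img[disk] <- 220
  set.seed(10)
  img <- img + matrix(stats::rnorm(nr * nr, 0, 5), nr, nr)
  q <- normalize_quantize(img, matrix(TRUE, nr, nr))
  cand <- spatial_fcm(q)
  thr <- oracle_otsu(as.numeric(q$patch))
  otsu_mask <- q$patch > thr
  jac <- sum(cand & otsu_mask) / sum(cand | otsu_mask)
  expect_gte(jac, 0.95)
  expect_gte(sum(cand & disk) / sum(cand | disk), 0.9)

  # determinism
  cand2 <- spatial_fcm(q)
  expect_identical(cand, cand2)
})

test_that("refinement keeps the largest component, fills holes, opens spurs", {
  m <- matrix(FALSE, 30, 30)
  m[5:18, 5:18] <- TRUE       # 196-pixel component
  m[10, 10] <- FALSE          # interior hole
  m[25:26, 25:27] <- TRUE     # small 6-pixel component
  r <- refine_mask(m)
  expect_false(r[25, 25])     # small component dropped
  expect_true(r[10, 10])      # hole filled
  # refinement output is confined to the (hole-filled) largest component of
  # its input: no pixels from other components or outside the main blob
  main <- habitex:::fill_holes(habitex:::largest_component(m))
  expect_true(all(which(r) %in% which(main)))
  expect_true(all(r[6:17, 6:17]))
  lab <- habitex:::label_components(unclass(r))
  expect_equal(max(lab), 1L)
  expect_error(refine_mask(matrix(FALSE, 5, 5)), "empty")
})

test_that("segmentation of a synthetic lesion overlaps the truth mask", {
  sc <- make_noiseless_study(seed = 11, grid = c(96L, 96L))
  seg <- segment_study(sc$study)
  expect_gte(dice_coefficient(seg$mask, sc$mask), 0.85)
  # pure function of the images: the cohort tag plays no role
  st2 <- sc$study
  st2$cohort <- "validation"
  seg2 <- segment_study(st2)
  expect_identical(seg$mask, seg2$mask)
})

test_that("slice selection maximizes enhancing area with earliest-index ties", {
  sc <- make_noiseless_study(seed = 14)
  expect_identical(select_slice(sc$study), 1L)

  # slices with controlled lesion areas: small / large / medium disks
  disk_study <- function(radius) {
    m <- outer(1:64, 1:64, function(r, c) (r - 32)^2 + (c - 32)^2 <= radius^2)
    ttp <- matrix(NA_integer_, 64, 64); ttp[m] <- 4L
    generate_study(m, ttp, kinetic_params(noise_sd = 0), seed = 1)
  }
  stack <- list(disk_study(5), disk_study(14), disk_study(9))
  expect_identical(select_slice(stack), 2L)

  # exact tie: identical slices -> smallest index
  expect_identical(select_slice(list(disk_study(9), disk_study(9))), 1L)
})
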