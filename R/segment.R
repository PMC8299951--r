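# Semi-automatic lesion segmentation on subtraction images: ROI
# normalization to mu +/- 3 sigma, 8-bit quantization, spatial fuzzy C-means,
# morphological refinement.

#' Subtraction series
#'
#' Subtracts the pre-contrast image from each of the 8 post-contrast images.
#' Values are kept signed.
#'
#' @param study A `dce_study` or list with `pre` and `post`.
#' @return R x C x 8 numeric array of subtraction images.
#' @export
subtract_phases <- function(study) {
  pre <- study$pre
  post <- study$post
  if (!identical(dim(pre), dim(post)[1:2]) || dim(post)[3] != 8L) {
    stop("pre and post images must share shape, with 8 post phases")
  }
  sweep(post, c(1, 2), pre, `-`)
}

round_half_up <- function(x) floor(x + 0.5)

#' Normalize and quantize an ROI to 8 bits
#'
#' Gray levels are clipped to `mu +/- 3 sigma` (mu, sigma computed over the
#' ROI pixels) and mapped linearly to 0..255 with round-half-up. The whole
#' ROI bounding box is quantized with the ROI-derived window so downstream
#' clustering sees the lesion and its immediate background on one scale.
#'
#' @param image Numeric matrix (typically one subtraction phase).
#' @param roi Logical matrix marking ROI pixels (same shape as `image`).
#' @return A `quantized_roi`: list with `patch` (integer matrix over the ROI
#'   bounding box, values 0..255), `roi_mask` (ROI cropped to the box),
#'   `box` (list of `rows`, `cols` in the image frame, 1-based), `mu`,
#'   `sigma`.
#' @export
normalize_quantize <- function(image, roi) {
  stopifnot(identical(dim(image), dim(roi)), is.logical(roi))
  vals <- image[roi]
  if (length(vals) < 16L) stop("ROI must contain at least 16 pixels")
  mu <- mean(vals)
  sigma <- stats::sd(vals)
  if (!is.finite(sigma) || sigma <= 0) {
    stop("degenerate ROI: zero variance inside the ROI")
  }
  rb <- range(which(rowSums(roi) > 0))
  cb <- range(which(colSums(roi) > 0))
  rows <- rb[1]:rb[2]; cols <- cb[1]:cb[2]
  sub <- image[rows, cols, drop = FALSE]
  lo <- mu - 3 * sigma
  clipped <- pmin(pmax(sub, lo), mu + 3 * sigma)
  patch <- round_half_up((clipped - lo) / (6 * sigma) * 255)
  storage.mode(patch) <- "integer"
  structure(list(
    patch = patch,
    roi_mask = roi[rows, cols, drop = FALSE],
    box = list(rows = rows, cols = cols),
    mu = mu, sigma = sigma
  ), class = "quantized_roi")
}

#' Spatial fuzzy C-means candidate mask
#'
#' Fuzzy C-means on the quantized gray levels with memberships smoothed by a
#' local mean window each iteration (spatial FCM). Centroids initialize
#' deterministically on an even grid of the 8-bit range, so runs are
#' reproducible without random restarts. The lesion is the cluster with the
#' brightest final centroid.
#'
#' @param qroi A [normalize_quantize()] result.
#' @param clusters Number of clusters (default 2: lesion vs background).
#' @param fuzziness Fuzzifier m (default 2).
#' @param window Odd side length of the membership-smoothing window.
#' @param tol Convergence threshold on the max membership change.
#' @param max_iter Iteration cap; non-convergence warns and returns the
#'   current assignment.
#' @param seed Accepted for interface stability; the deterministic
#'   initialization makes it inert.
#' @return Logical candidate mask in the full image frame implied by
#'   `qroi$box` (attribute `box`), cropped representation in `qroi` frame.
#' @export
spatial_fcm <- function(qroi, clusters = 2L, fuzziness = 2,
                        window = 3L, tol = 1e-5, max_iter = 100L,
                        seed = 0L) {
  stopifnot(inherits(qroi, "quantized_roi"))
  x <- as.numeric(qroi$patch)
  nr <- nrow(qroi$patch); nc <- ncol(qroi$patch)
  k <- as.integer(clusters)
  v <- 256 * (seq_len(k) - 0.5) / k  # {64, 192} for k = 2
  m <- fuzziness
  half <- (window - 1L) %/% 2L
  smooth <- function(u) {
    # mean filter over the window, per cluster
    um <- matrix(u, nr, nc)
    acc <- matrix(0, nr, nc); wt <- matrix(0, nr, nc)
    for (dr in -half:half) for (dc in -half:half) {
      acc <- acc + shift_mat(um, dr, dc, fill = 0)
      wt <- wt + shift_mat(matrix(1, nr, nc), dr, dc, fill = 0)
    }
    as.numeric(acc / wt)
  }
  u <- matrix(1 / k, length(x), k)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d2 <- outer(x, v, function(a, b) (a - b)^2)
    d2 <- pmax(d2, 1e-12)
    w <- d2^(-1 / (m - 1))
    u_new <- w / rowSums(w)
    for (j in seq_len(k)) u_new[, j] <- smooth(u_new[, j])
    u_new <- u_new / rowSums(u_new)
    um <- u_new^m
    v <- as.numeric(crossprod(um, x) / colSums(um))
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("spatial FCM did not converge; returning current assignment")
  assign <- max.col(u, ties.method = "first")
  lesion_cluster <- which.max(v)
  cand <- matrix(assign == lesion_cluster, nr, nc)
  attr(cand, "box") <- qroi$box
  attr(cand, "centroids") <- v
  cand
}

#' Morphological refinement of a candidate mask
#'
#' Keeps the largest 4-connected component, fills interior holes, applies a
#' binary opening with the 3x3 cross, and keeps the largest remaining
#' component so the result is a single connected lesion.
#'
#' @param mask Logical candidate mask.
#' @return Logical lesion mask (class `lesion_mask`); attributes of the
#'   input (e.g. `box`) are preserved.
#' @export
refine_mask <- function(mask) {
  if (!any(mask)) stop("refine_mask: empty candidate mask")
  box <- attr(mask, "box")
  out <- largest_component(mask)
  out <- fill_holes(out)
  out <- open_cross(out)
  if (!any(out)) stop("segmentation failure: mask empty after opening")
  out <- largest_component(out)
  out <- fill_holes(out)
  attr(out, "box") <- box
  class(out) <- c("lesion_mask", class(out))
  out
}

# Otsu threshold on a numeric vector (histogram over 256 bins).
otsu_threshold <- function(vals) {
  rng <- range(vals)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(255L, as.integer((vals - rng[1]) / diff(rng) * 256)) + 1L,
                nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  t_bin <- which.max(sigma_b)
  rng[1] + t_bin / 256 * diff(rng)
}

#' Select the slice with the largest enhancing lesion
#'
#' Automated surrogate for reader slice selection: for a stack of slices the
#' index whose phase-4 subtraction image has the largest candidate lesion
#' area (pixels above the slice's Otsu threshold) is returned; ties break to
#' the smallest index. A single 2D study bypasses to index 1.
#'
#' @param studies A single `dce_study` (returns 1) or list of `dce_study`
#'   slices.
#' @return Integer slice index (1-based).
#' @export
select_slice <- function(studies) {
  if (inherits(studies, "dce_study")) return(1L)
  areas <- vapply(studies, function(s) {
    sub4 <- subtract_phases(s)[, , 4]
    thr <- otsu_threshold(as.numeric(sub4))
    sum(sub4 > thr)
  }, numeric(1))
  if (all(areas == 0)) stop("segmentation failure: no enhancing region on any slice")
  which.max(areas)  # ties -> first (smallest index)
}

#' Segment one study end to end
#'
#' Convenience wrapper: phase-4 subtraction, ROI selection (default: the
#' truth-adjacent bounding box padded by 10 pixels, standing in for a
#' hand-drawn ROI), normalization/quantization, spatial FCM, morphological
#' refinement.
#'
#' @param study A `dce_study`.
#' @param roi Optional logical ROI matrix; defaults to the truth bounding box
#'   padded by `roi_pad` pixels.
#' @param phase Subtraction phase used for segmentation (default 4).
#' @param roi_pad Padding around the truth bounding box, pixels.
#' @param ... Passed to [spatial_fcm()].
#' @return List with `mask` (full-frame logical lesion mask), `qroi`, and
#'   `sub` (the phase subtraction image).
#' @export
segment_study <- function(study, roi = NULL, phase = 4L, roi_pad = 10L, ...) {
  sub <- subtract_phases(study)[, , phase]
  if (is.null(roi)) {
    tm <- study$truth$mask
    if (is.null(tm)) stop("no ROI given and study carries no truth mask")
    rb <- range(which(rowSums(tm) > 0))
    cb <- range(which(colSums(tm) > 0))
    roi <- matrix(FALSE, nrow(sub), ncol(sub))
    roi[max(1, rb[1] - roi_pad):min(nrow(sub), rb[2] + roi_pad),
        max(1, cb[1] - roi_pad):min(ncol(sub), cb[2] + roi_pad)] <- TRUE
  }
  qroi <- normalize_quantize(sub, roi)
  cand <- spatial_fcm(qroi, ...)
  refined <- refine_mask(cand)
  full <- matrix(FALSE, nrow(sub), ncol(sub))
  full[qroi$box$rows, qroi$box$cols] <- refined
  list(mask = full, qroi = qroi, sub = sub)
}
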