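# Texture feature extraction from a masked, 8-bit-quantized image region:
# first-order histogram moments, gray-level co-occurrence (GLCM), gray-level
# run-length (GRLM) and discrete wavelet subband magnitudes. The canonical
# schema has 467 features per region: 4 + 380 + 44 + 3 x 13.

.glcm_angles <- c(0L, 45L, 90L, 135L)
.glcm_distances <- 1:4
.glcm_stat_names <- c(
  "autocorrelation", "contrast", "correlation", "cluster_prominence",
  "cluster_shade", "dissimilarity", "energy", "entropy", "homogeneity",
  "max_probability", "sum_of_squares", "sum_average", "sum_variance",
  "sum_entropy", "difference_variance", "difference_entropy", "imc1",
  "idn", "idmn"
)
.grlm_stat_names <- c(
  "sre", "lre", "gln", "rln", "rp", "lgre", "hgre",
  "srlge", "srhge", "lrlge", "lrhge"
)
.dwt_wavelets <- c("haar", "db2", "sym4")

angle_offset <- function(angle, distance) {
  # (row, col) displacement; rows grow downward
  switch(as.character(angle),
    "0" = c(0L, distance),
    "45" = c(-distance, distance),
    "90" = c(-distance, 0L),
    "135" = c(-distance, -distance),
    stop("angle must be one of 0, 45, 90, 135")
  )
}

#' First-order histogram features
#'
#' Population moments of the gray levels in a region: mean, variance,
#' skewness and kurtosis (non-excess, Pearson). A zero-variance region
#' reports skewness and kurtosis of 0 by convention; an empty region yields
#' `NA` for all four.
#'
#' @param values Numeric vector of region gray levels.
#' @return Named numeric vector `hist_mean`, `hist_variance`,
#'   `hist_skewness`, `hist_kurtosis`.
#' @export
histogram_features <- function(values) {
  out <- c(hist_mean = NA_real_, hist_variance = NA_real_,
           hist_skewness = NA_real_, hist_kurtosis = NA_real_)
  n <- length(values)
  if (n == 0L) return(out)
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  out["hist_mean"] <- mu
  out["hist_variance"] <- m2
  if (m2 <= 0) {
    out["hist_skewness"] <- 0
    out["hist_kurtosis"] <- 0
  } else {
    out["hist_skewness"] <- mean((values - mu)^3) / m2^1.5
    out["hist_kurtosis"] <- mean((values - mu)^4) / m2^2
  }
  out
}

#' Gray-level co-occurrence matrix
#'
#' Counts pairs of gray levels at a fixed displacement, restricted to pairs
#' whose both pixels lie inside the mask, symmetrized (each pair counted in
#' both directions) and normalized to a probability matrix.
#'
#' @param patch Integer matrix of quantized gray levels in `[0, levels - 1]`.
#' @param mask Logical matrix, same shape as `patch`.
#' @param angle One of 0, 45, 90, 135 (degrees).
#' @param distance Offset length in pixels.
#' @param levels Number of gray levels (default 256).
#' @return `levels x levels` probability matrix (class `cooc_matrix`), or
#'   `NULL` when the offset admits no valid pair.
#' @export
glcm <- function(patch, mask, angle, distance = 1L, levels = 256L) {
  stopifnot(identical(dim(patch), dim(mask)))
  off <- angle_offset(angle, as.integer(distance))
  nr <- nrow(patch); nc <- ncol(patch)
  r1 <- seq_len(nr); c1 <- seq_len(nc)
  r1 <- r1[r1 + off[1] >= 1L & r1 + off[1] <= nr]
  c1 <- c1[c1 + off[2] >= 1L & c1 + off[2] <= nc]
  if (!length(r1) || !length(c1)) return(NULL)
  a <- patch[r1, c1, drop = FALSE]
  b <- patch[r1 + off[1], c1 + off[2], drop = FALSE]
  ok <- mask[r1, c1, drop = FALSE] & mask[r1 + off[1], c1 + off[2], drop = FALSE]
  if (!any(ok)) return(NULL)
  av <- a[ok]; bv <- b[ok]
  L <- as.integer(levels)
  counts <- tabulate(av + bv * L + 1L, nbins = L * L)
  M <- matrix(counts, L, L)
  M <- M + t(M)
  P <- M / sum(M)
  class(P) <- c("cooc_matrix", class(P))
  P
}

#' Haralick-type statistics of a co-occurrence matrix
#'
#' The 19 second-order statistics of the feature schema, computed with level
#' indices 1..L, natural-log entropies and the 0 log 0 = 0 convention.
#' Sum variance is taken about the sum average; correlation and the
#' information measure of correlation fall back to 0 when their denominators
#' degenerate (single-level region).
#'
#' @param P Probability matrix from [glcm()] (or `NULL`).
#' @return Named numeric vector of 19 statistics (`NA` if `P` is `NULL`).
#' @export
glcm_stats <- function(P) {
  out <- stats::setNames(rep(NA_real_, length(.glcm_stat_names)),
                         .glcm_stat_names)
  if (is.null(P)) return(out)
  L <- nrow(P)
  nz <- which(P > 0)
  p <- P[nz]
  i <- (nz - 1L) %% L + 1L   # row level index
  j <- (nz - 1L) %/% L + 1L  # col level index
  px <- rowSums(P); py <- colSums(P)
  mu_x <- sum(seq_len(L) * px); mu_y <- sum(seq_len(L) * py)
  sd_x <- sqrt(sum((seq_len(L) - mu_x)^2 * px))
  sd_y <- sqrt(sum((seq_len(L) - mu_y)^2 * py))
  dif <- abs(i - j)
  s <- i + j

  out["autocorrelation"] <- sum(i * j * p)
  out["contrast"] <- sum((i - j)^2 * p)
  out["correlation"] <- if (sd_x * sd_y > 0) {
    (sum(i * j * p) - mu_x * mu_y) / (sd_x * sd_y)
  } else 0
  out["cluster_prominence"] <- sum((s - mu_x - mu_y)^4 * p)
  out["cluster_shade"] <- sum((s - mu_x - mu_y)^3 * p)
  out["dissimilarity"] <- sum(dif * p)
  out["energy"] <- sum(p^2)
  out["entropy"] <- -sum(p * log(p))
  out["homogeneity"] <- sum(p / (1 + dif))
  out["max_probability"] <- max(p)
  out["sum_of_squares"] <- sum((i - mu_x)^2 * p)

  p_sum <- tapply(p, s, sum)
  k_sum <- as.numeric(names(p_sum))
  sum_avg <- sum(k_sum * p_sum)
  out["sum_average"] <- sum_avg
  out["sum_variance"] <- sum((k_sum - sum_avg)^2 * p_sum)
  out["sum_entropy"] <- -sum(p_sum * log(p_sum))

  p_dif <- tapply(p, dif, sum)
  k_dif <- as.numeric(names(p_dif))
  mu_d <- sum(k_dif * p_dif)
  out["difference_variance"] <- sum((k_dif - mu_d)^2 * p_dif)
  out["difference_entropy"] <- -sum(p_dif * log(p_dif))

  hxy <- out[["entropy"]]
  hxy1 <- -sum(p * log(px[i] * py[j]))
  ent_marg <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  hx <- ent_marg(px); hy <- ent_marg(py)
  out["imc1"] <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0

  out["idn"] <- sum(p / (1 + dif / L))
  out["idmn"] <- sum(p / (1 + (i - j)^2 / L^2))
  out
}

#' Full GLCM feature block (380 values)
#'
#' For each of the 19 statistics: one value per (angle, distance) map
#' (4 x 4 = 16) plus one per angle-averaged matrix at each distance (4),
#' i.e. 20 variants per statistic. The angle-averaged value is the statistic
#' of the mean of the four directional probability matrices.
#'
#' @inheritParams glcm
#' @return Named numeric vector of 380 values; offsets with no valid pair
#'   yield `NA` for their statistics.
#' @export
glcm_block <- function(patch, mask, levels = 256L) {
  vals <- numeric(0)
  stats_by <- list()
  for (d in .glcm_distances) {
    mats <- lapply(.glcm_angles, function(a) glcm(patch, mask, a, d, levels))
    avg <- if (any(vapply(mats, is.null, logical(1)))) NULL else {
      Reduce(`+`, mats) / length(mats)
    }
    for (k in seq_along(.glcm_angles)) {
      stats_by[[paste0("a", .glcm_angles[k], "_d", d)]] <- glcm_stats(mats[[k]])
    }
    stats_by[[paste0("amean_d", d)]] <- glcm_stats(avg)
  }
  out <- numeric(0)
  for (stat in .glcm_stat_names) {
    for (d in .glcm_distances) {
      for (tok in c(paste0("a", .glcm_angles), "amean")) {
        key <- paste0(tok, "_d", d)
        out[paste0("glcm_", stat, "_", key)] <- stats_by[[key]][[stat]]
      }
    }
  }
  out
}

#' Gray-level run-length matrix
#'
#' Counts maximal constant-gray-level runs along one direction, truncated at
#' mask boundaries (a run never crosses a background pixel).
#'
#' @inheritParams glcm
#' @param angle One of 0 (horizontal), 45, 90 (vertical), 135 degrees;
#'   distance is fixed at 1 pixel.
#' @return Matrix of run counts indexed by (gray level 1..levels, run length),
#'   with attribute `npixels` = region pixel count; `NULL` for an empty
#'   region.
#' @export
grlm <- function(patch, mask, angle, levels = 256L) {
  stopifnot(identical(dim(patch), dim(mask)))
  if (!any(mask)) return(NULL)
  nr <- nrow(patch); nc <- ncol(patch)
  lines_idx <- switch(as.character(angle),
    "0" = lapply(seq_len(nr), function(r) cbind(r, seq_len(nc))),
    "90" = lapply(seq_len(nc), function(c) cbind(seq_len(nr), c)),
    "45" = lapply(2:(nr + nc), function(sm) {
      r <- seq(min(sm - 1L, nr), max(1L, sm - nc))  # bottom-left to top-right
      cbind(r, sm - r)
    }),
    "135" = lapply((1L - nc):(nr - 1L), function(df) {
      r <- seq(max(1L, 1L + df), min(nr, nc + df))  # top-left to bottom-right
      cbind(r, r - df)
    }),
    stop("angle must be one of 0, 45, 90, 135")
  )
  lev_run <- list()
  max_len <- 0L
  runs_g <- integer(0); runs_l <- integer(0)
  for (ln in lines_idx) {
    idx <- (ln[, 2] - 1L) * nr + ln[, 1]
    mv <- mask[idx]
    if (!any(mv)) next
    vals <- ifelse(mv, patch[idx], NA_integer_)
    r <- rle(vals)
    keep <- !is.na(r$values)
    runs_g <- c(runs_g, r$values[keep])
    runs_l <- c(runs_l, r$lengths[keep])
  }
  if (!length(runs_g)) return(NULL)
  max_len <- max(runs_l)
  R <- matrix(0L, as.integer(levels), max_len)
  for (k in seq_along(runs_g)) {
    R[runs_g[k] + 1L, runs_l[k]] <- R[runs_g[k] + 1L, runs_l[k]] + 1L
  }
  attr(R, "npixels") <- sum(mask)
  R
}

#' Run-length statistics (Galloway/Chu)
#'
#' Eleven run-length statistics with gray levels indexed 1..L. "Fraction of
#' image in runs" is the run percentage: number of runs over region pixels.
#'
#' @param R Run-length matrix from [grlm()] (or `NULL`).
#' @return Named numeric vector of 11 statistics (`NA` if `R` is `NULL`).
#' @export
grlm_stats <- function(R) {
  out <- stats::setNames(rep(NA_real_, length(.grlm_stat_names)),
                         .grlm_stat_names)
  if (is.null(R)) return(out)
  nz <- which(R > 0)
  r <- as.numeric(R[nz])
  i <- (nz - 1L) %% nrow(R) + 1L  # gray level index 1..L
  l <- (nz - 1L) %/% nrow(R) + 1L # run length
  N <- sum(r)
  np <- attr(R, "npixels")
  out["sre"] <- sum(r / l^2) / N
  out["lre"] <- sum(r * l^2) / N
  out["gln"] <- sum(tapply(r, i, sum)^2) / N
  out["rln"] <- sum(tapply(r, l, sum)^2) / N
  out["rp"] <- N / np
  out["lgre"] <- sum(r / i^2) / N
  out["hgre"] <- sum(r * i^2) / N
  out["srlge"] <- sum(r / (i^2 * l^2)) / N
  out["srhge"] <- sum(r * i^2 / l^2) / N
  out["lrlge"] <- sum(r * l^2 / i^2) / N
  out["lrhge"] <- sum(r * i^2 * l^2) / N
  out
}

#' Full GRLM feature block (44 values)
#'
#' Eleven statistics at four angles, distance 1.
#'
#' @inheritParams glcm
#' @return Named numeric vector of 44 values.
#' @export
grlm_block <- function(patch, mask, levels = 256L) {
  out <- numeric(0)
  stats_by <- lapply(.glcm_angles, function(a) {
    grlm_stats(grlm(patch, mask, a, levels))
  })
  names(stats_by) <- paste0("a", .glcm_angles)
  for (stat in .grlm_stat_names) {
    for (tok in names(stats_by)) {
      out[paste0("grlm_", stat, "_", tok)] <- stats_by[[tok]][[stat]]
    }
  }
  out
}

#' Wavelet subband features for one wavelet family (13 values)
#'
#' The masked bounding box of the region is filled with the region mean
#' outside the mask, padded with the region mean to the next multiple of 16,
#' and decomposed over 4 levels. Each of the 12 detail subbands (scales 1-4 x
#' horizontal/vertical/diagonal) contributes its mean absolute coefficient,
#' plus the scale-4 approximation subband: 13 values.
#'
#' @inheritParams glcm
#' @param wavelet One of `"haar"`, `"db2"`, `"sym4"`.
#' @param boundary Passed to [dwt2()].
#' @return Named numeric vector of 13 values, e.g. `dwt_haar_2HH`
#'   (horizontal detail, scale 2) and `dwt_haar_4LL`; `NA` for an empty
#'   region.
#' @export
dwt_features <- function(patch, mask, wavelet = c("haar", "db2", "sym4"),
                         boundary = "symmetric") {
  wavelet <- match.arg(wavelet)
  nm <- c(paste0("dwt_", wavelet, "_",
                 rep(1:4, each = 3), rep(c("HH", "VH", "DH"), 4)),
          paste0("dwt_", wavelet, "_4LL"))
  out <- stats::setNames(rep(NA_real_, 13L), nm)
  if (!any(mask)) return(out)
  rb <- range(which(rowSums(mask) > 0))
  cb <- range(which(colSums(mask) > 0))
  sub <- patch[rb[1]:rb[2], cb[1]:cb[2], drop = FALSE]
  msk <- mask[rb[1]:rb[2], cb[1]:cb[2], drop = FALSE]
  mu <- mean(sub[msk])
  filled <- sub
  filled[!msk] <- mu
  tr <- 16L * ceiling(nrow(filled) / 16L)
  tc <- 16L * ceiling(ncol(filled) / 16L)
  padded <- matrix(mu, tr, tc)
  padded[seq_len(nrow(filled)), seq_len(ncol(filled))] <- filled
  dec <- dwt2(padded, wavelet, levels = 4L, boundary = boundary)
  k <- 1L
  for (lev in 1:4) {
    for (b in c("H", "V", "D")) {
      out[k] <- mean(abs(dec[[lev]][[b]]))
      k <- k + 1L
    }
  }
  out[13L] <- mean(abs(dec$LL))
  out
}

#' Canonical 467-feature schema
#'
#' @return Character vector of the 467 canonical feature names, in order:
#'   histogram (4), GLCM (380), GRLM (44), DWT (39).
#' @export
feature_schema <- function() {
  hist_nm <- c("hist_mean", "hist_variance", "hist_skewness", "hist_kurtosis")
  glcm_nm <- character(0)
  for (stat in .glcm_stat_names) {
    for (d in .glcm_distances) {
      glcm_nm <- c(glcm_nm, paste0(
        "glcm_", stat, "_", c(paste0("a", .glcm_angles), "amean"), "_d", d))
    }
  }
  grlm_nm <- character(0)
  for (stat in .grlm_stat_names) {
    grlm_nm <- c(grlm_nm, paste0("grlm_", stat, "_a", .glcm_angles))
  }
  dwt_nm <- character(0)
  for (w in .dwt_wavelets) {
    dwt_nm <- c(dwt_nm,
                paste0("dwt_", w, "_", rep(1:4, each = 3),
                       rep(c("HH", "VH", "DH"), 4)),
                paste0("dwt_", w, "_4LL"))
  }
  c(hist_nm, glcm_nm, grlm_nm, dwt_nm)
}

#' Extract the full 467-feature vector for one region
#'
#' @inheritParams glcm
#' @return Named numeric vector of 467 features in canonical schema order.
#'   An empty region yields all-`NA` values with attribute `missing = TRUE`.
#' @export
extract_features <- function(patch, mask, levels = 256L) {
  schema <- feature_schema()
  if (!any(mask)) {
    out <- stats::setNames(rep(NA_real_, length(schema)), schema)
    attr(out, "missing") <- TRUE
    return(out)
  }
  vals <- c(
    histogram_features(as.numeric(patch[mask])),
    glcm_block(patch, mask, levels),
    grlm_block(patch, mask, levels),
    unlist(lapply(.dwt_wavelets, function(w) dwt_features(patch, mask, w)))
  )
  out <- vals[schema]
  names(out) <- schema
  attr(out, "missing") <- FALSE
  out
}
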