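# Internal helpers: seeded RNG, binary morphology on matrices, random fields.

# Run code under a derived RNG stream without touching the caller's RNG.
# Substream seeds are derived additively; offsets keep streams apart.
local_seed_eval <- function(seed, expr) {
  withr::with_seed(as.integer(seed %% .Machine$integer.max), expr)
}

derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647L)
}

# Shift a matrix by (dr, dc), padding with `fill`.
shift_mat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r_src <- seq_len(nr) - dr
  c_src <- seq_len(nc) - dc
  r_ok <- r_src >= 1 & r_src <= nr
  c_ok <- c_src >= 1 & c_src <= nc
  out[r_ok, c_ok] <- m[r_src[r_ok], c_src[c_ok]]
  out
}

# Label 4-connected components of a logical matrix. Returns integer matrix,
# 0 = background, components numbered from 1 in first-encounter order.
label_components <- function(mask) {
  stopifnot(is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue
      queue <- integer(0)
      r <- (p - 1L) %% nr + 1L
      c <- (p - 1L) %/% nr + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1]; cc <- c + d[2]
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        q <- (cc[ok] - 1L) * nr + rr[ok]
        q <- q[mask[q] & lab[q] == 0L]
        if (length(q)) {
          q <- unique(q)
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

largest_component <- function(mask) {
  lab <- label_components(mask)
  if (all(lab == 0L)) return(mask & FALSE)
  counts <- tabulate(lab[lab > 0L])
  lab == which.max(counts)
}

# Fill interior holes: background pixels not 4-connected to the border.
fill_holes <- function(mask) {
  bg <- !mask
  nr <- nrow(mask); nc <- ncol(mask)
  border <- bg
  border[2:(nr - 1), 2:(nc - 1)] <- FALSE
  seed <- border
  lab <- label_components(bg)
  reach <- unique(lab[seed & lab > 0L])
  outside <- matrix(lab %in% reach, nr, nc) & bg
  mask | (bg & !outside)
}

erode_cross <- function(mask) {
  mask &
    shift_mat(mask, -1L, 0L) & shift_mat(mask, 1L, 0L) &
    shift_mat(mask, 0L, -1L) & shift_mat(mask, 0L, 1L)
}

dilate_cross <- function(mask) {
  mask |
    shift_mat(mask, -1L, 0L) | shift_mat(mask, 1L, 0L) |
    shift_mat(mask, 0L, -1L) | shift_mat(mask, 0L, 1L)
}

open_cross <- function(mask) dilate_cross(erode_cross(mask))

# Dilate a mask n times with the 3x3 cross (used to pad ROI boxes).
dilate_n <- function(mask, n) {
  for (i in seq_len(n)) mask <- dilate_cross(mask)
  mask
}

# Smooth Gaussian random field on an nr x nc grid: white noise convolved with a
# separable Gaussian kernel of standard deviation `corr_len` pixels, then
# standardized to zero mean / unit variance. corr_len ~ 0 returns white noise.
gaussian_field <- function(nr, nc, corr_len) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (corr_len > 1e-8) {
    half <- max(1L, ceiling(3 * corr_len))
    k <- stats::dnorm(seq(-half, half), sd = corr_len)
    k <- k / sum(k)
    pad <- function(m, n) {
      top <- m[rep(1L, n), , drop = FALSE]
      bot <- m[rep(nrow(m), n), , drop = FALSE]
      rbind(top, m, bot)
    }
    conv_rows <- function(m) {
      mp <- pad(m, half)
      out <- matrix(0, nrow(m), ncol(m))
      for (j in seq_along(k)) {
        out <- out + k[j] * mp[seq_len(nrow(m)) + (j - 1L), , drop = FALSE]
      }
      out
    }
    z <- conv_rows(z)
    z <- t(conv_rows(t(z)))
  }
  (z - mean(z)) / max(stats::sd(z), 1e-12)
}

#' Dice overlap coefficient between two masks
#'
#' @param a,b Logical matrices of identical shape.
#' @return `2|A∩B| / (|A|+|B|)`; `NA` when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  inter <- sum(a & b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NA_real_)
  2 * inter / denom
}
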