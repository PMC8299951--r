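# Separable 2D discrete wavelet transform (Mallat pyramid) for the texture
# extractor. Orthonormal analysis filter banks; the high-pass is the quadrature
# mirror of the low-pass, h[k] = (-1)^k g[L-1-k].

.wavelet_lo <- list(
  haar = c(1, 1) / sqrt(2),
  db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
  sym4 = c(
    -0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
    0.80373875180591614, 0.29785779560527736, -0.09921954357684722,
    -0.01260396726203783, 0.03222310060404270
  )
)

wavelet_filters <- function(wavelet = c("haar", "db2", "sym4")) {
  wavelet <- match.arg(wavelet)
  g <- .wavelet_lo[[wavelet]]
  L <- length(g)
  h <- (-1)^(seq_len(L) - 1) * rev(g)
  list(lo = g, hi = h, length = L)
}

# One analysis step along a vector: filter + downsample by 2.
# boundary = "periodic": circular indexing, output length n/2 (n even) -- the
# transform is exactly orthonormal (Parseval holds).
# boundary = "symmetric": half-sample symmetric extension (…x2 x1 | x1 x2…),
# implemented by reflecting indices with period 2n so that filters longer
# than the signal (deep decomposition levels) remain well defined.
dwt_step_1d <- function(x, filt, boundary) {
  n <- length(x)
  L <- filt$length
  if (n %% 2L != 0L) stop("DWT step needs even length")
  if (boundary == "periodic") {
    pos <- outer(seq(0L, n - 2L, by = 2L), seq_len(L) - 1L, `+`) %% n + 1L
  } else {
    p <- outer(seq(0L, n - 2L, by = 2L), seq_len(L) - 1L - (L %/% 2L - 1L),
               `+`)
    q <- p %% (2L * n)
    pos <- ifelse(q < n, q, 2L * n - 1L - q) + 1L
  }
  xm <- matrix(x[pos], nrow = nrow(pos))
  list(
    a = as.vector(xm %*% filt$lo),
    d = as.vector(xm %*% filt$hi)
  )
}

# One 2D analysis level: rows then columns; returns LL, LH (horizontal detail),
# HL (vertical detail), HH (diagonal detail).
dwt_level_2d <- function(m, filt, boundary) {
  # transform columns (vertical filtering)
  lo_c <- apply(m, 2, function(v) dwt_step_1d(v, filt, boundary)$a)
  hi_c <- apply(m, 2, function(v) dwt_step_1d(v, filt, boundary)$d)
  if (!is.matrix(lo_c)) lo_c <- matrix(lo_c, nrow = 1)
  if (!is.matrix(hi_c)) hi_c <- matrix(hi_c, nrow = 1)
  trans_rows <- function(mm, which) {
    out <- apply(mm, 1, function(v) dwt_step_1d(v, filt, boundary)[[which]])
    if (!is.matrix(out)) out <- matrix(out, ncol = 1)
    t(out)
  }
  list(
    LL = trans_rows(lo_c, "a"),
    H = trans_rows(lo_c, "d"),  # horizontal high-frequency detail
    V = trans_rows(hi_c, "a"),  # vertical high-frequency detail
    D = trans_rows(hi_c, "d")   # diagonal detail
  )
}

#' Multilevel 2D discrete wavelet decomposition
#'
#' Mallat pyramid decomposition of a numeric matrix with an orthonormal
#' wavelet. Used internally by [dwt_features()]; exposed for testing and
#' inspection.
#'
#' @param m Numeric matrix.
#' @param wavelet One of `"haar"`, `"db2"`, `"sym4"`.
#' @param levels Number of decomposition levels (default 4).
#' @param boundary `"symmetric"` (default) or `"periodic"`. With periodic
#'   boundary on a dyadic matrix the transform is orthonormal, so the sum of
#'   squared coefficients equals the sum of squared input values.
#' @return List with one element per level, each holding `H`, `V`, `D` detail
#'   matrices, plus `LL` (final approximation).
#' @export
dwt2 <- function(m, wavelet = c("haar", "db2", "sym4"), levels = 4L,
                 boundary = c("symmetric", "periodic")) {
  wavelet <- match.arg(wavelet)
  boundary <- match.arg(boundary)
  filt <- wavelet_filters(wavelet)
  out <- vector("list", levels)
  cur <- m
  for (lev in seq_len(levels)) {
    if (min(dim(cur)) < 1L) stop("dwt2: matrix exhausted before requested level")
    dec <- dwt_level_2d(cur, filt, boundary)
    out[[lev]] <- dec[c("H", "V", "D")]
    cur <- dec$LL
  }
  out$LL <- cur
  out
}
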