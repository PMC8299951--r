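# Independent brute-force oracles used to check the fast implementations.
# These deliberately use naive enumeration, not the package's code paths.

# Co-occurrence by explicit enumeration of every pixel pair.
oracle_glcm <- function(patch, mask, angle, distance, levels) {
  off <- switch(as.character(angle),
    "0" = c(0L, distance), "45" = c(-distance, distance),
    "90" = c(-distance, 0L), "135" = c(-distance, -distance))
  M <- matrix(0, levels, levels)
  nr <- nrow(patch); nc <- ncol(patch)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + off[1]; c2 <- c + off[2]
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    if (!mask[r, c] || !mask[r2, c2]) next
    i <- patch[r, c] + 1L; j <- patch[r2, c2] + 1L
    M[i, j] <- M[i, j] + 1
    M[j, i] <- M[j, i] + 1
  }
  if (sum(M) == 0) return(NULL)
  M / sum(M)
}

# Run-length counts by explicit line scanning.
oracle_grlm <- function(patch, mask, angle, levels) {
  nr <- nrow(patch); nc <- ncol(patch)
  step <- switch(as.character(angle),
    "0" = c(0L, 1L), "45" = c(-1L, 1L), "90" = c(1L, 0L), "135" = c(1L, 1L))
  starts <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    pr <- r - step[1]; pc <- c - step[2]
    if (pr < 1 || pr > nr || pc < 1 || pc > nc) {
      starts[[length(starts) + 1L]] <- c(r, c)
    }
  }
  runs <- list()
  for (s in starts) {
    r <- s[1]; c <- s[2]
    cur_val <- NA; cur_len <- 0L
    while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
      v <- if (mask[r, c]) patch[r, c] else NA
      if (!is.na(v) && !is.na(cur_val) && v == cur_val) {
        cur_len <- cur_len + 1L
      } else {
        if (!is.na(cur_val)) runs[[length(runs) + 1L]] <- c(cur_val, cur_len)
        cur_val <- v; cur_len <- if (is.na(v)) 0L else 1L
      }
      r <- r + step[1]; c <- c + step[2]
    }
    if (!is.na(cur_val)) runs[[length(runs) + 1L]] <- c(cur_val, cur_len)
  }
  if (!length(runs)) return(NULL)
  rr <- do.call(rbind, runs)
  R <- matrix(0L, levels, max(rr[, 2]))
  for (k in seq_len(nrow(rr))) {
    R[rr[k, 1] + 1L, rr[k, 2]] <- R[rr[k, 1] + 1L, rr[k, 2]] + 1L
  }
  attr(R, "npixels") <- sum(mask)
  R
}

# AUC by exhaustive concordant/discordant/tied pair counting.
oracle_auc <- function(scores, labels) {
  pos <- which(labels == "malignant")
  neg <- which(labels == "benign")
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

# Otsu threshold by exhaustive scan over candidate cuts.
oracle_otsu <- function(vals) {
  cand <- sort(unique(vals))
  best <- -Inf; thr <- cand[1]
  for (t in cand[-length(cand)]) {
    g1 <- vals[vals <= t]; g2 <- vals[vals > t]
    bc <- length(g1) * length(g2) / length(vals)^2 * (mean(g1) - mean(g2))^2
    if (bc > best) { best <- bc; thr <- t }
  }
  thr
}

# Tiny noiseless study builder shared by several tests.
make_noiseless_study <- function(seed = 5, grid = c(64L, 64L),
                                 mixture = rep(1 / 8, 8)) {
  mask <- generate_lesion(seed, grid)
  kin <- kinetic_params(ttp_mixture = mixture, noise_sd = 0)
  ttp <- assign_ttp(mask, mixture, seed + 1L)
  study <- generate_study(mask, ttp, kin, seed + 2L)
  list(study = study, mask = mask, ttp = ttp, kin = kin)
}
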