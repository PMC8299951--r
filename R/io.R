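# Lightweight image exports for QC review.

#' Write a binary mask as a PNG file
#'
#' Foreground pixels are written as white (255), background as black.
#'
#' @param mask Logical matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.logical(mask))
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Write a subregion map as a color-coded PNG
#'
#' Background is black; the early, moderate and late habitats are red,
#' green and blue.
#'
#' @param sm A [partition_subregions()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_subregion_png <- function(sm, path) {
  stopifnot(inherits(sm, "subregion_map"))
  z <- sm$zone
  img <- array(0, dim = c(nrow(z), ncol(z), 3))
  img[, , 1][z == 1L] <- 1  # early: red
  img[, , 2][z == 2L] <- 1  # moderate: green
  img[, , 3][z == 3L] <- 1  # late: blue
  png::writePNG(img, path)
  invisible(path)
}
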