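# Image file I/O. Images live in the package as plain numeric arrays:
# H x W matrices (grayscale) or H x W x 3 arrays (color), 8-bit intensity
# range [0, 255]. EBImage stores pixels [x, y(, c)] in [0, 1]; these helpers
# do the transposition and scaling in one place.

.toEB <- function(img) {
  if (is.matrix(img)) EBImage::Image(t(img) / 255)
  else EBImage::Image(aperm(img, c(2L, 1L, 3L)) / 255,
                      colormode = EBImage::Color)
}

.fromEB <- function(eb) {
  d <- EBImage::imageData(eb)
  nd <- length(dim(d))
  if (nd == 2L) return(roundHalfUp(clampRange(t(d) * 255, 0, 255)))
  if (dim(d)[3] >= 3L) d <- d[, , 1:3, drop = FALSE]
  else if (dim(d)[3] == 1L) return(roundHalfUp(clampRange(t(d[, , 1]) * 255, 0, 255)))
  roundHalfUp(clampRange(aperm(d, c(2L, 1L, 3L)) * 255, 0, 255))
}

#' Read a raster image file
#'
#' Reads PNG, TIFF or JPEG into the package's plain-array representation:
#' a numeric `height x width` matrix (grayscale) or `height x width x 3`
#' array (color) with intensities in `[0, 255]`. Alpha channels are dropped.
#'
#' @param path file path.
#' @return numeric matrix or 3-channel array.
#' @export
readImageFile <- function(path) {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path))
  eb <- tryCatch(suppressWarnings(EBImage::readImage(path)),
                 error = function(e)
                   stop(sprintf("cannot read image '%s': %s",
                                path, conditionMessage(e)), call. = FALSE))
  .fromEB(eb)
}

#' Write an image or a binary mask as PNG
#'
#' `writeImagePNG()` writes an 8-bit grayscale or color image;
#' `writeMaskPNG()` writes a logical mask as a 0/255 binary PNG.
#'
#' @param img numeric matrix or `H x W x 3` array, intensities in `[0, 255]`.
#' @param mask logical matrix.
#' @param path output file path (`.png`).
#' @return the path, invisibly.
#' @export
writeImagePNG <- function(img, path) {
  checkImage(img)
  EBImage::writeImage(.toEB(img), path, type = "png")
  invisible(path)
}

#' @rdname writeImagePNG
#' @export
writeMaskPNG <- function(mask, path) {
  mask <- asLogicalMask(mask)
  EBImage::writeImage(EBImage::Image(t(mask) * 1), path, type = "png")
  invisible(path)
}

#' Read a binary mask PNG
#'
#' Pixels above half intensity are foreground.
#'
#' @param path file path of a 0/255 PNG mask.
#' @return logical matrix.
#' @export
readMaskPNG <- function(path) {
  img <- readImageFile(path)
  if (!is.matrix(img)) img <- toGrayscale(img)
  img > 127.5
}
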