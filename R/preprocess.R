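# Shared preprocessing front-end: grayscale conversion, clip-limited
# adaptive histogram enhancement, and dermoscopic hair removal. All six
# segmentation pipelines run behind this front-end.

#' Convert a color image to grayscale
#'
#' Luma conversion `G = 0.3 R + 0.59 G + 0.11 B`, rounded half-up to an
#' integer 8-bit level. Grayscale input passes through unchanged.
#'
#' @param img numeric `H x W` matrix or `H x W x 3` array in `[0, 255]`.
#' @return numeric `H x W` matrix.
#' @examples
#' toGrayscale(array(c(255, 0, 0), c(1, 1, 3)))  # pure red -> 77
#' @export
toGrayscale <- function(img) {
  checkImage(img)
  if (is.matrix(img)) return(img)
  g <- 0.3 * img[, , 1] + 0.59 * img[, , 2] + 0.11 * img[, , 3]
  matrix(roundHalfUp(g), dim(img)[1], dim(img)[2])
}

#' Construct enhancement parameters
#'
#' Parameters of the clip-limited adaptive histogram enhancement: the image
#' is split into a `tileRows x tileCols` grid; each tile's `nBins`-bin
#' histogram is clipped at `clipMultiplier` times its average bin occupancy
#' (tile pixel count / `nBins`), the clipped excess is redistributed
#' uniformly, and tile equalization mappings are blended bilinearly.
#'
#' @param clipMultiplier clip limit as a multiple of the average bin
#'   occupancy; must be >= 1 so the clip limit is never below the average.
#'   Default 4.
#' @param tileRows,tileCols tile grid (default 8 x 8).
#' @param nBins histogram bins (default 256).
#' @return a validated list of class `"EnhanceParams"`.
#' @export
enhanceParams <- function(clipMultiplier = 4, tileRows = 8, tileCols = 8,
                          nBins = 256) {
  if (clipMultiplier < 1) stop("'clipMultiplier' must be >= 1")
  if (tileRows < 1 || tileCols < 1) stop("tile dimensions must be >= 1")
  if (nBins < 1) stop("'nBins' must be >= 1")
  structure(list(clipMultiplier = clipMultiplier,
                 tileRows = as.integer(tileRows),
                 tileCols = as.integer(tileCols),
                 nBins = as.integer(nBins)),
            class = "EnhanceParams")
}

# Tile boundary index: chunk 1..n into k nearly equal contiguous runs.
.tileBounds <- function(n, k) {
  lo <- floor((seq_len(k) - 1) * n / k) + 1L
  hi <- floor(seq_len(k) * n / k)
  cbind(lo = lo, hi = hi)
}

#' Average histogram occupancy per tile
#'
#' The per-tile mean number of pixels per histogram bin (tile pixel count /
#' `nBins`), the quantity from which the clip limit is derived.
#'
#' @param img grayscale image matrix.
#' @param params an [enhanceParams()] list.
#' @return `tileRows x tileCols` numeric matrix.
#' @export
averagePixels <- function(img, params = enhanceParams()) {
  checkImage(img)
  if (!is.matrix(img)) stop("'img' must be grayscale (use toGrayscale first)")
  h <- nrow(img); w <- ncol(img)
  if (params$tileRows > h || params$tileCols > w)
    stop("invalid params: tile grid produces empty regions for this image")
  rb <- .tileBounds(h, params$tileRows)
  cb <- .tileBounds(w, params$tileCols)
  npix <- outer(rb[, "hi"] - rb[, "lo"] + 1L, cb[, "hi"] - cb[, "lo"] + 1L)
  npix / params$nBins
}

#' Clip-limited adaptive histogram enhancement
#'
#' Per tile, the intensity histogram is clipped at the clip limit
#' (`clipMultiplier` x average occupancy), excess mass is redistributed
#' uniformly across bins, and the clipped CDF defines a monotone intensity
#' mapping to `[0, 255]`; per-pixel output bilinearly blends the mappings of
#' the four surrounding tile centers. Shape and 8-bit bounds are preserved.
#'
#' @param img grayscale image matrix in `[0, 255]`.
#' @param params an [enhanceParams()] list.
#' @return enhanced image matrix, same shape.
#' @export
enhanceImage <- function(img, params = enhanceParams()) {
  checkImage(img)
  if (!is.matrix(img)) stop("'img' must be grayscale (use toGrayscale first)")
  h <- nrow(img); w <- ncol(img)
  tr <- params$tileRows; tc <- params$tileCols; nb <- params$nBins
  if (tr > h || tc > w)
    stop("invalid params: tile grid produces empty regions for this image")
  rb <- .tileBounds(h, tr)
  cb <- .tileBounds(w, tc)
  binOf <- matrix(pmin(nb - 1L, floor(img / 256 * nb)), h, w)  # bin indices

  # per-tile clipped-CDF mappings: (tr*tc) x nb matrix of output levels
  maps <- matrix(0, tr * tc, nb)
  for (i in seq_len(tr)) for (j in seq_len(tc)) {
    tile <- binOf[rb[i, 1]:rb[i, 2], cb[j, 1]:cb[j, 2]]
    n <- length(tile)
    hist <- tabulate(as.vector(tile) + 1L, nbins = nb)
    cl <- max(1, params$clipMultiplier * n / nb)
    clipped <- pmin(hist, cl)
    clipped <- clipped + (n - sum(clipped)) / nb     # uniform redistribution
    maps[(i - 1L) * tc + j, ] <- 255 * cumsum(clipped) / sum(clipped)
  }

  # bilinear blend between the four surrounding tile-center mappings
  centerOf <- function(b) (b[, 1] + b[, 2]) / 2
  rc <- centerOf(rb); cc <- centerOf(cb)
  interpIdx <- function(pos, centers) {
    k <- length(centers)
    hi <- pmin(k, findInterval(pos, centers) + 1L)
    lo <- pmax(1L, hi - 1L)
    span <- centers[hi] - centers[lo]
    wHi <- ifelse(span > 0, (pos - centers[lo]) / span, 0)
    wHi <- clampRange(wHi, 0, 1)
    list(lo = lo, hi = hi, wHi = wHi)
  }
  ri <- interpIdx(seq_len(h), rc)
  ci <- interpIdx(seq_len(w), cc)

  bins <- as.vector(binOf) + 1L
  rLo <- rep(ri$lo, times = w); rHi <- rep(ri$hi, times = w)
  rW  <- rep(ri$wHi, times = w)
  cLo <- rep(ci$lo, each = h);  cHi <- rep(ci$hi, each = h)
  cW  <- rep(ci$wHi, each = h)
  tidx <- function(r, c) (r - 1L) * tc + c
  val <- (1 - rW) * (1 - cW) * maps[cbind(tidx(rLo, cLo), bins)] +
         (1 - rW) * cW       * maps[cbind(tidx(rLo, cHi), bins)] +
         rW       * (1 - cW) * maps[cbind(tidx(rHi, cLo), bins)] +
         rW       * cW       * maps[cbind(tidx(rHi, cHi), bins)]
  matrix(roundHalfUp(clampRange(val, 0, 255)), h, w)
}

#' Remove hair-like occlusions from a dermoscopic image
#'
#' Detects dark curvilinear structures by a morphological blackhat (closing
#' minus image) on the grayscale channel, thresholds the response with
#' Otsu's method -- guarded by an absolute floor and by a noise-adaptive
#' floor (a multiple of the robust pixel-noise scale estimated from the
#' median-filter residual), so hairless but noisy images are left
#' essentially untouched -- dilates the detection by one pixel, and fills
#' the detected pixels by iterative neighborhood inpainting. Pixels outside
#' the dilated hair mask are unchanged.
#'
#' @param img numeric `H x W` matrix or `H x W x 3` array in `[0, 255]`.
#'   Grayscale input is processed on its single channel.
#' @param brushSize diameter of the disc structuring element (default 7,
#'   covering curves up to ~3 px wide).
#' @param responseFloor minimum blackhat response (intensity units) for a
#'   pixel to count as hair (default 10).
#' @param noiseMultiplier the response must also exceed this multiple of
#'   the estimated noise standard deviation (default 5).
#' @return image of the same shape and channel count.
#' @export
removeHair <- function(img, brushSize = 7, responseFloor = 10,
                       noiseMultiplier = 5) {
  checkImage(img)
  gray <- toGrayscale(img)
  eb <- EBImage::Image(t(gray) / 255)
  brush <- EBImage::makeBrush(brushSize, shape = "disc")
  bh <- EBImage::closing(eb, brush) - eb            # blackhat, >= 0
  bhMat <- t(EBImage::imageData(bh)) * 255
  med <- t(EBImage::imageData(EBImage::medianFilter(eb, 1))) * 255
  sigmaHat <- 1.4826 * stats::mad(as.vector(gray - med), center = 0)
  floorEff <- max(responseFloor, noiseMultiplier * sigmaHat)
  if (max(bhMat) < floorEff) return(img)
  thr <- EBImage::otsu(EBImage::Image(t(bhMat) / 255)) * 255
  hair <- bhMat > max(thr, floorEff)
  if (!any(hair)) return(img)
  hair <- t(EBImage::imageData(EBImage::dilate(
    EBImage::Image(t(hair) * 1), EBImage::makeBrush(3, "box")))) > 0.5

  inpaint <- function(ch) {
    x <- ch
    x[hair] <- NA
    # hairs are thin: a handful of diffusion passes fills them
    for (pass in seq_len(50L)) {
      nas <- which(is.na(x), arr.ind = TRUE)
      if (nrow(nas) == 0L) break
      h <- nrow(x); w <- ncol(x)
      fill <- numeric(nrow(nas)); cnt <- numeric(nrow(nas))
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                     c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))) {
        rr <- nas[, 1] + d[1]; cc <- nas[, 2] + d[2]
        ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
        v <- rep(NA_real_, nrow(nas))
        v[ok] <- x[cbind(rr[ok], cc[ok])]
        good <- !is.na(v)
        fill[good] <- fill[good] + v[good]
        cnt[good] <- cnt[good] + 1
      }
      ready <- cnt > 0
      if (!any(ready)) break
      x[nas[ready, , drop = FALSE]] <- fill[ready] / cnt[ready]
    }
    x[is.na(x)] <- ch[is.na(x)]                     # unreachable safety net
    roundHalfUp(clampRange(x, 0, 255))
  }

  if (is.matrix(img)) return(inpaint(img))
  out <- img
  for (c in 1:3) out[, , c] <- inpaint(img[, , c])
  out
}

#' Full preprocessing front-end
#'
#' The chain every segmentation method shares: hair removal (by default only
#' for color input, where the artifact occurs), grayscale conversion, and
#' clip-limited adaptive histogram enhancement.
#'
#' @param img image matrix or 3-channel array in `[0, 255]`.
#' @param hairRemoval `"auto"` (color input only), `"on"`, or `"off"`.
#' @param enhance logical; apply [enhanceImage()] (default `TRUE`).
#' @param params an [enhanceParams()] list.
#' @return preprocessed grayscale matrix.
#' @export
preprocessImage <- function(img, hairRemoval = c("auto", "on", "off"),
                            enhance = TRUE, params = enhanceParams()) {
  hairRemoval <- match.arg(hairRemoval)
  checkImage(img)
  doHair <- switch(hairRemoval, on = TRUE, off = FALSE,
                   auto = !is.matrix(img))
  if (doHair) img <- removeHair(img)
  gray <- toGrayscale(img)
  if (enhance) gray <- enhanceImage(gray, params)
  gray
}
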