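# Synthetic phantom generator. Phantoms emulate the difficulties of the
# four target modalities (MRI, microscopy, dermoscopy, CT) -- compact bright
# regions of interest, uneven illumination, Gaussian noise, and hair-like
# occluding curves -- while carrying an exactly known ground-truth mask, so
# every segmentation stage is testable without external data.

#' Construct a PhantomSpec
#'
#' Defaults describe a generic modality: a single bright elliptical region
#' (lesion / tumor / nucleus) on a darker background with moderate noise and
#' a mild illumination ramp. Use [phantomPreset()] for modality-flavoured
#' settings.
#'
#' @param width,height canvas size in pixels (>= 16). Default 256 x 256, the
#'   size to which this framework's input images are conventionally resized.
#' @param nBlobs number of elliptical foreground blobs (default 1: one ROI
#'   per image, as in single-lesion modalities).
#' @param blobIntensityMean,backgroundIntensityMean clean 8-bit levels of
#'   foreground and background (defaults 180 / 60).
#' @param noiseSigma Gaussian noise standard deviation in intensity units
#'   (default 15).
#' @param illuminationGradient fractional intensity drop from the left to
#'   the right edge, in `[0, 1]` (default 0.15).
#' @param hairCount number of dark occluding curves (default 0; dermoscopy
#'   presets use more).
#' @param seed RNG seed; the generator is a pure function of (spec, seed).
#' @return a validated [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec(width = 64, height = 64, noiseSigma = 0,
#'                     illuminationGradient = 0, seed = 7)
#' sample <- generatePhantom(spec)
#' table(phantomImage(sample))
#' @export
phantomSpec <- function(width = 256, height = 256, nBlobs = 1,
                        blobIntensityMean = 180,
                        backgroundIntensityMean = 60,
                        noiseSigma = 15, illuminationGradient = 0.15,
                        hairCount = 0, seed = 1) {
  new("PhantomSpec", width = as.integer(width), height = as.integer(height),
      nBlobs = as.integer(nBlobs),
      blobIntensityMean = as.numeric(blobIntensityMean),
      backgroundIntensityMean = as.numeric(backgroundIntensityMean),
      noiseSigma = as.numeric(noiseSigma),
      illuminationGradient = as.numeric(illuminationGradient),
      hairCount = as.integer(hairCount), seed = as.integer(seed))
}

#' Modality-flavoured phantom presets
#'
#' Returns the argument list of a [phantomSpec()] emulating the salient
#' difficulty of each imaging modality. Intensity statistics are the
#' package's own choices (no claim of matching any real dataset): `mri` has
#' strong noise, `micro` a high-contrast compact nucleus, `skin` hair
#' occlusion and an uneven-illumination ramp, `ct` low noise and a small
#' bright nodule.
#'
#' @param modality one of `"mri"`, `"micro"`, `"skin"`, `"ct"`.
#' @param ... overrides merged over the preset (e.g. `seed`).
#' @return a [PhantomSpec-class].
#' @export
phantomPreset <- function(modality = c("mri", "micro", "skin", "ct"), ...) {
  modality <- match.arg(modality)
  base <- switch(modality,
    mri   = list(blobIntensityMean = 200, backgroundIntensityMean = 40,
                 noiseSigma = 25, illuminationGradient = 0.1, hairCount = 0),
    micro = list(blobIntensityMean = 220, backgroundIntensityMean = 110,
                 noiseSigma = 10, illuminationGradient = 0.05, hairCount = 0),
    skin  = list(blobIntensityMean = 170, backgroundIntensityMean = 90,
                 noiseSigma = 15, illuminationGradient = 0.3, hairCount = 5),
    ct    = list(blobIntensityMean = 190, backgroundIntensityMean = 70,
                 noiseSigma = 8, illuminationGradient = 0.05, hairCount = 0))
  do.call(phantomSpec, utils::modifyList(base, list(...)))
}

# Draw one ellipse fully inside the frame; returns its logical footprint.
.drawEllipse <- function(width, height) {
  m <- min(width, height)
  for (try in seq_len(100L)) {
    a  <- stats::runif(1, 0.10, 0.22) * m   # semi-axes, pixels
    b  <- stats::runif(1, 0.10, 0.22) * m
    th <- stats::runif(1, 0, pi)
    r  <- max(a, b)
    cx <- stats::runif(1, 1 + r, width - r)
    cy <- stats::runif(1, 1 + r, height - r)
    if (cx - r >= 1 && cx + r <= width && cy - r >= 1 && cy + r <= height) {
      dx <- matrix(rep(seq_len(width), each = height), nrow = height) - cx
      dy <- matrix(rep(seq_len(height), width), nrow = height) - cy
      u <- (dx * cos(th) + dy * sin(th)) / a
      v <- (-dx * sin(th) + dy * cos(th)) / b
      return(u * u + v * v <= 1)
    }
  }
  stop("could not place an ellipse inside the frame")  # unreachable for valid specs
}

# Paint hairCount dark cubic Bezier curves over img (in place semantics).
.drawHairs <- function(img, hairCount) {
  h <- nrow(img); w <- ncol(img)
  for (k in seq_len(hairCount)) {
    # endpoints on opposite frame margins, control points anywhere inside
    vertical <- stats::runif(1) < 0.5
    if (vertical) {
      p0 <- c(1, stats::runif(1, 1, w)); p3 <- c(h, stats::runif(1, 1, w))
    } else {
      p0 <- c(stats::runif(1, 1, h), 1); p3 <- c(stats::runif(1, 1, h), w)
    }
    p1 <- c(stats::runif(1, 1, h), stats::runif(1, 1, w))
    p2 <- c(stats::runif(1, 1, h), stats::runif(1, 1, w))
    width_px <- sample(1:3, 1)
    level <- stats::runif(1, 5, 35)
    t <- seq(0, 1, length.out = 4L * max(h, w))
    bez <- function(i) (1 - t)^3 * p0[i] + 3 * (1 - t)^2 * t * p1[i] +
      3 * (1 - t) * t^2 * p2[i] + t^3 * p3[i]
    rr <- roundHalfUp(bez(1)); cc <- roundHalfUp(bez(2))
    offs <- switch(width_px, `1` = 0L, `2` = 0:1, `3` = -1:1)
    for (dr in offs) for (dc in offs) {
      r2 <- rr + dr; c2 <- cc + dc
      keep <- r2 >= 1 & r2 <= h & c2 >= 1 & c2 <= w
      img[cbind(r2[keep], c2[keep])] <- level
    }
  }
  img
}

#' Generate one phantom sample
#'
#' Renders clean elliptical blobs at `blobIntensityMean` on a
#' `backgroundIntensityMean` background, applies a linear left-to-right
#' illumination ramp, adds Gaussian noise, draws optional hair curves over
#' the image (never into the mask), and clips to `[0, 255]`. The truth mask
#' marks blob interiors before any corruption.
#'
#' @param spec a [PhantomSpec-class] (see [phantomSpec()]).
#' @return a [PhantomSample-class].
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  h <- spec@height; w <- spec@width
  withSeed(spec@seed, {
    mask <- matrix(FALSE, h, w)
    for (b in seq_len(spec@nBlobs))
      mask <- mask | .drawEllipse(w, h)
    img <- matrix(spec@backgroundIntensityMean, h, w)
    img[mask] <- spec@blobIntensityMean
    # linear illumination ramp, scale 1 at the left edge, 1 - g at the right
    if (w > 1) {
      ramp <- 1 - spec@illuminationGradient * (seq_len(w) - 1) / (w - 1)
      img <- sweep(img, 2, ramp, `*`)
    }
    # noise draws always happen so that the RNG stream (and hence blob and
    # hair placement) is identical across noiseSigma settings of one seed
    noise <- matrix(stats::rnorm(h * w), h, w)
    img <- img + spec@noiseSigma * noise
    if (spec@hairCount > 0L) img <- .drawHairs(img, spec@hairCount)
    img <- roundHalfUp(clampRange(img, 0, 255))
    new("PhantomSample", image = img, truthMask = mask, spec = spec)
  })
}

#' Generate benchmark sets of phantoms
#'
#' Produces one set of phantom samples per requested size, mirroring
#' image-count sweep benchmarks. Each sample's seed is derived from the
#' master seed by a counter-based scheme, so a sample's content depends only
#' on its (set, index) coordinates, never on iteration order; samples differ
#' in blob placement and noise draw.
#'
#' @param specTemplate a [PhantomSpec-class] whose fields (except `seed`)
#'   are shared by all samples.
#' @param counts integer vector of set sizes, each >= 1.
#' @param seed master seed.
#' @return named list (one element per count) of lists of
#'   [PhantomSample-class] objects.
#' @examples
#' sets <- generateBenchmarkSet(phantomSpec(width = 32, height = 32),
#'                              counts = c(2, 3), seed = 1)
#' lengths(sets)
#' @export
generateBenchmarkSet <- function(specTemplate, counts, seed = 1) {
  stopifnot(is(specTemplate, "PhantomSpec"))
  if (length(counts) == 0) stop("'counts' must be non-empty")
  counts <- as.integer(counts)
  if (any(counts < 1L)) stop("every set size in 'counts' must be >= 1")
  sets <- vector("list", length(counts))
  names(sets) <- as.character(counts)
  for (s in seq_along(counts)) {
    sets[[s]] <- lapply(seq_len(counts[s]), function(i) {
      sp <- specTemplate
      sp@seed <- deriveSeed(seed, (s - 1L) * 1000000 + i)
      generatePhantom(sp)
    })
  }
  sets
}

#' Write / read a phantom sample as paired files
#'
#' `writePhantomSample()` writes `<stem>.png` (image), `<stem>_mask.png`
#' (0/255 binary truth) and `<stem>.json` (the spec);
#' `readPhantomSample()` reads them back.
#'
#' @param sample a [PhantomSample-class].
#' @param stem output path stem (no extension).
#' @return the stem, invisibly (`writePhantomSample`); a
#'   [PhantomSample-class] (`readPhantomSample`).
#' @export
writePhantomSample <- function(sample, stem) {
  stopifnot(is(sample, "PhantomSample"))
  writeImagePNG(sample@image, paste0(stem, ".png"))
  writeMaskPNG(sample@truthMask, paste0(stem, "_mask.png"))
  sp <- sample@spec
  fields <- list(width = sp@width, height = sp@height, nBlobs = sp@nBlobs,
                 blobIntensityMean = sp@blobIntensityMean,
                 backgroundIntensityMean = sp@backgroundIntensityMean,
                 noiseSigma = sp@noiseSigma,
                 illuminationGradient = sp@illuminationGradient,
                 hairCount = sp@hairCount, seed = sp@seed)
  jsonlite::write_json(fields, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname writePhantomSample
#' @export
readPhantomSample <- function(stem) {
  fields <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  spec <- do.call(phantomSpec, fields)
  new("PhantomSample",
      image = toGrayscale(readImageFile(paste0(stem, ".png"))),
      truthMask = readMaskPNG(paste0(stem, "_mask.png")),
      spec = spec)
}
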