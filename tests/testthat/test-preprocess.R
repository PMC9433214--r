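test_that("grayscale conversion applies the 0.3/0.59/0.11 luma weights half-up", {
  px <- function(r, g, b) array(c(r, g, b), c(1, 1, 3))
  expect_equal(toGrayscale(px(255, 255, 255))[1, 1], 255)
  expect_equal(toGrayscale(px(0, 0, 0))[1, 1], 0)
  expect_equal(toGrayscale(px(255, 0, 0))[1, 1], 77)   # 76.5 rounds up
  expect_equal(toGrayscale(px(0, 255, 0))[1, 1], 150)  # 150.45
  expect_equal(toGrayscale(px(0, 0, 255))[1, 1], 28)   # 28.05
})

test_that("grayscale passes 1-channel input through and is idempotent", {
  m <- matrix(c(0, 128, 37, 255), 2, 2)
  expect_identical(toGrayscale(m), m)
  rgb <- array(runif(4 * 4 * 3, 0, 255), c(4, 4, 3))
  g <- toGrayscale(rgb)
  expect_identical(toGrayscale(g), g)
  expect_error(toGrayscale(array(0, c(4, 4, 2))), "channels")
})

test_that("average histogram occupancy is region pixel count over bin count", {
  img64 <- matrix(0, 64, 64)
  expect_equal(averagePixels(img64, enhanceParams(tileRows = 1,
                                                  tileCols = 1))[1, 1], 16)
  img256 <- matrix(0, 256, 256)
  expect_equal(averagePixels(img256, enhanceParams(tileRows = 1,
                                                   tileCols = 1))[1, 1], 256)
  expect_equal(averagePixels(img64, enhanceParams(tileRows = 1, tileCols = 1,
                                                  nBins = 1))[1, 1], 4096)
  ap <- averagePixels(img64, enhanceParams(tileRows = 8, tileCols = 8))
  expect_equal(dim(ap), c(8, 8))
  expect_equal(sum(ap) * 256, 64 * 64)
  expect_error(averagePixels(matrix(0, 4, 4),
                             enhanceParams(tileRows = 8, tileCols = 8)),
               "empty region")
})

test_that("enhancement maps a constant image to a constant image", {
  for (cm in c(1, 4, 100)) {
    e <- enhanceImage(matrix(77, 32, 32), enhanceParams(clipMultiplier = cm,
                                                        tileRows = 4,
                                                        tileCols = 4))
    expect_length(unique(as.vector(e)), 1)
    expect_equal(dim(e), c(32, 32))
  }
})

test_that("unclipped single-region enhancement equals textbook histogram equalization", {
  set.seed(41)
  img <- matrix(sample(0:255, 64 * 64, TRUE, prob = (1:256)^1.5), 64, 64)
  got <- enhanceImage(img, enhanceParams(clipMultiplier = 1e9, tileRows = 1,
                                         tileCols = 1))
  # independent oracle: m(v) = round(255 * cdf(v) / N)
  h <- tabulate(as.vector(img) + 1L, 256)
  mapv <- floor(255 * cumsum(h) / sum(h) + 0.5)
  oracle <- matrix(mapv[img + 1L], 64, 64)
  expect_identical(got, oracle)
})

test_that("enhancement expands the contrast of a two-level phantom", {
  s <- generatePhantom(phantomSpec(width = 96, height = 96,
                                   blobIntensityMean = 160,
                                   backgroundIntensityMean = 80,
                                   noiseSigma = 0, illuminationGradient = 0,
                                   seed = 2))
  e <- enhanceImage(phantomImage(s), enhanceParams(tileRows = 1,
                                                   tileCols = 1))
  outGap <- min(e[truthMask(s)]) - max(e[!truthMask(s)])
  expect_gt(outGap, 160 - 80)
})

test_that("enhancement preserves shape and bounds, with monotone tile mappings", {
  set.seed(5)
  img <- matrix(sample(0:255, 48 * 80, TRUE), 48, 80)
  e <- enhanceImage(img)
  expect_equal(dim(e), c(48, 80))
  expect_gte(min(e), 0)
  expect_lte(max(e), 255)
  # monotone mapping: with a single region the output is a pure function of
  # the input value; probe it over the full 8-bit ramp
  ramp <- matrix(rep(0:255, each = 2), 2, 256)
  for (cm in c(1, 2, 4, 50)) {
    p <- enhanceParams(clipMultiplier = cm, tileRows = 1, tileCols = 1)
    vals <- enhanceImage(ramp, p)[1, ]
    expect_true(all(diff(vals) >= 0))
  }
})

test_that("hair removal is a near-no-op on hairless phantoms and on black images", {
  s0 <- generatePhantom(phantomSpec(width = 96, height = 96, noiseSigma = 5,
                                    illuminationGradient = 0, hairCount = 0,
                                    seed = 4))
  out <- removeHair(phantomImage(s0))
  expect_lt(mean(out != phantomImage(s0)), 0.01)
  black <- matrix(0, 32, 32)
  expect_identical(removeHair(black), black)
})

test_that("hair removal reduces the error against the paired hairless render", {
  spH <- phantomSpec(width = 96, height = 96, noiseSigma = 5,
                     illuminationGradient = 0, hairCount = 5, seed = 4)
  sp0 <- phantomSpec(width = 96, height = 96, noiseSigma = 5,
                     illuminationGradient = 0, hairCount = 0, seed = 4)
  hairy <- phantomImage(generatePhantom(spH))
  clean <- phantomImage(generatePhantom(sp0))
  maeBefore <- mean(abs(hairy - clean))
  maeAfter <- mean(abs(removeHair(hairy) - clean))
  expect_lt(maeAfter, maeBefore)
})

test_that("hair removal handles 3-channel input and keeps the channel count", {
  spH <- phantomSpec(width = 48, height = 48, noiseSigma = 0,
                     illuminationGradient = 0, hairCount = 3, seed = 6)
  g <- phantomImage(generatePhantom(spH))
  rgb <- array(rep(g, 3), c(48, 48, 3))
  out <- removeHair(rgb)
  expect_equal(dim(out), c(48, 48, 3))
  expect_gte(min(out), 0)
  expect_lte(max(out), 255)
})

test_that("the preprocessing front-end composes to a grayscale image", {
  s <- generatePhantom(phantomSpec(width = 48, height = 48, seed = 3))
  pre <- preprocessImage(phantomImage(s))
  expect_true(is.matrix(pre))
  expect_equal(dim(pre), c(48, 48))
  preRaw <- preprocessImage(phantomImage(s), enhance = FALSE)
  expect_identical(preRaw, phantomImage(s))
})
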