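test_that("noiseless single-blob phantom is exactly two-level with matching mask", {
  s <- twoLevelPhantom(seed = 3, size = 64, fg = 180, bg = 60)
  img <- phantomImage(s)
  expect_setequal(unique(as.vector(img)), c(60, 180))
  expect_identical(img == 180, truthMask(s))
  nf <- sum(truthMask(s))
  expect_gt(nf, 0)
  expect_lt(nf, length(img))
})

test_that("generation is a pure function of (spec, seed)", {
  sp <- phantomSpec(width = 48, height = 48, noiseSigma = 12,
                    illuminationGradient = 0.2, hairCount = 3, seed = 11)
  a <- generatePhantom(sp)
  b <- generatePhantom(sp)
  expect_identical(phantomImage(a), phantomImage(b))
  expect_identical(truthMask(a), truthMask(b))
  sp2 <- phantomSpec(width = 48, height = 48, noiseSigma = 12,
                     illuminationGradient = 0.2, hairCount = 3, seed = 12)
  expect_false(identical(phantomImage(a),
                         phantomImage(generatePhantom(sp2))))
})

test_that("noise has the requested scale and does not shift blob placement", {
  spN <- phantomSpec(width = 96, height = 96, noiseSigma = 10,
                     illuminationGradient = 0, hairCount = 0, seed = 1)
  sp0 <- phantomSpec(width = 96, height = 96, noiseSigma = 0,
                     illuminationGradient = 0, hairCount = 0, seed = 1)
  noisy <- generatePhantom(spN)
  clean <- generatePhantom(sp0)
  expect_identical(truthMask(noisy), truthMask(clean))
  diff <- phantomImage(noisy) - phantomImage(clean)
  unclipped <- phantomImage(noisy) > 0 & phantomImage(noisy) < 255
  expect_lt(abs(sd(diff[unclipped]) - 10) / 10, 0.2)
})

test_that("intensities are clipped to [0, 255] even under extreme settings", {
  sp <- phantomSpec(width = 32, height = 32, blobIntensityMean = 250,
                    backgroundIntensityMean = 5, noiseSigma = 80, seed = 5)
  img <- phantomImage(generatePhantom(sp))
  expect_gte(min(img), 0)
  expect_lte(max(img), 255)
})

test_that("hair curves darken the image but never touch the mask", {
  spH <- phantomSpec(width = 64, height = 64, noiseSigma = 0,
                     illuminationGradient = 0, hairCount = 4, seed = 9)
  sp0 <- phantomSpec(width = 64, height = 64, noiseSigma = 0,
                     illuminationGradient = 0, hairCount = 0, seed = 9)
  withHair <- generatePhantom(spH)
  without <- generatePhantom(sp0)
  expect_identical(truthMask(withHair), truthMask(without))
  changed <- phantomImage(withHair) != phantomImage(without)
  expect_gt(sum(changed), 0)
  expect_true(all(phantomImage(withHair)[changed] <
                    phantomImage(without)[changed]))
})

test_that("invalid specs fail validation naming the offending field", {
  expect_error(phantomSpec(width = 8), "width")
  expect_error(phantomSpec(blobIntensityMean = 300), "blobIntensityMean")
  expect_error(phantomSpec(blobIntensityMean = 60,
                           backgroundIntensityMean = 60), "differ")
  expect_error(phantomSpec(illuminationGradient = 1.5),
               "illuminationGradient")
})

test_that("benchmark sets have requested sizes, distinct members, and are reproducible", {
  tpl <- phantomSpec(width = 32, height = 32)
  sets <- generateBenchmarkSet(tpl, counts = c(5, 10), seed = 21)
  expect_named(sets, c("5", "10"))
  expect_length(sets[["5"]], 5)
  expect_length(sets[["10"]], 10)
  imgs <- lapply(sets[["5"]], phantomImage)
  for (i in 1:4) for (j in (i + 1):5)
    expect_false(identical(imgs[[i]], imgs[[j]]))
  again <- generateBenchmarkSet(tpl, counts = c(5, 10), seed = 21)
  expect_identical(lapply(sets[["10"]], phantomImage),
                   lapply(again[["10"]], phantomImage))
  expect_error(generateBenchmarkSet(tpl, counts = integer(0)), "non-empty")
})

test_that("phantom samples round-trip through paired PNG + JSON files", {
  s <- generatePhantom(phantomSpec(width = 40, height = 40, noiseSigma = 10,
                                   seed = 4))
  stem <- file.path(withr::local_tempdir(), "sample")
  writePhantomSample(s, stem)
  expect_true(all(file.exists(paste0(stem, c(".png", "_mask.png", ".json")))))
  back <- readPhantomSample(stem)
  expect_identical(phantomImage(back), phantomImage(s))
  expect_identical(truthMask(back), truthMask(s))
  expect_equal(phantomSpecOf(back)@noiseSigma, 10)
})

test_that("modality presets build valid specs with their salient features", {
  skin <- phantomPreset("skin", seed = 2)
  expect_gt(skin@hairCount, 0)
  mri <- phantomPreset("mri", width = 64, height = 64)
  expect_s4_class(generatePhantom(mri), "PhantomSample")
  expect_gt(mri@noiseSigma, phantomPreset("ct")@noiseSigma)
})
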