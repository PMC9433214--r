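# Refiner tests run on small phantoms so the whole file stays in tens of
# seconds on one CPU.

smallSamples <- function(n, seed = 3, size = 48, noise = 15, ramp = 0.1) {
  generateBenchmarkSet(phantomSpec(width = size, height = size,
                                   noiseSigma = noise,
                                   illuminationGradient = ramp),
                       counts = n, seed = seed)[[1]]
}

test_that("training reduces the loss on noisy phantoms", {
  samples <- smallSamples(20, seed = 14)
  tr <- trainRefiner(samples, "kmeans", config = refinerConfig(epochs = 5),
                     seed = 2)
  expect_length(tr$report@lossTrace, 5)
  expect_lt(tail(tr$report@lossTrace, 1), tr$report@lossTrace[1])
  expect_s4_class(tr$model, "RefinerModel")
  expect_identical(tr$model@proposalMethod, "kmeans")
})

test_that("truth-as-proposal training learns the identity shortcut", {
  samples <- smallSamples(24, seed = 5)
  tr <- trainRefiner(samples, "kmeans", config = refinerConfig(epochs = 8),
                     seed = 1, proposals = lapply(samples, truthMask))
  expect_gte(tail(tr$report@valDiceTrace, 1), 0.99)
})

test_that("training is deterministic given seed and config", {
  samples <- smallSamples(20, seed = 8, size = 32)
  a <- trainRefiner(samples, "fcm", config = refinerConfig(epochs = 3),
                    seed = 6)
  b <- trainRefiner(samples, "fcm", config = refinerConfig(epochs = 3),
                    seed = 6)
  expect_identical(a$report@lossTrace, b$report@lossTrace)
  expect_identical(a$model@layers, b$model@layers)
})

test_that("training guards its preconditions", {
  samples <- smallSamples(20, seed = 9, size = 32)
  expect_error(trainRefiner(samples[1:5], "kmeans"), "at least 20")
  expect_error(trainRefiner(samples, "kmeans",
                            config = refinerConfig(epochs = 0)), "epochs")
  empty <- lapply(samples, function(s) matrix(FALSE, 32, 32))
  expect_error(trainRefiner(samples, "kmeans", proposals = empty),
               "every proposal mask .* empty")
})

test_that("refineMask thresholds behave monotonically with sane boundaries", {
  samples <- smallSamples(20, seed = 11, size = 32)
  tr <- trainRefiner(samples, "kmeans", config = refinerConfig(epochs = 2),
                     seed = 3)
  s <- samples[[1]]
  pre <- preprocessImage(phantomImage(s))
  proposal <- truthMask(s)
  allFg <- refineMask(tr$model, pre, proposal, threshold = 0)
  expect_true(all(allFg))
  expect_warning(none <- refineMask(tr$model, pre, proposal, threshold = 1),
                 "empty ROI")
  expect_false(any(none))
  prev <- allFg
  for (th in c(0.25, 0.5, 0.75)) {
    cur <- suppressWarnings(refineMask(tr$model, pre, proposal,
                                       threshold = th))
    expect_true(all(prev | !cur))  # raising threshold never grows the set
    prev <- cur
  }
  expect_error(refineMask(tr$model, pre, matrix(TRUE, 8, 8)), "contract")
})

test_that("models round-trip through disk with bit-identical forward passes", {
  samples <- smallSamples(20, seed = 12, size = 32)
  tr <- trainRefiner(samples, "kmeans", config = refinerConfig(epochs = 2),
                     seed = 4)
  s <- samples[[2]]
  pre <- preprocessImage(phantomImage(s))
  pm <- truthMask(s)
  path <- withr::local_tempfile(fileext = ".rds")
  saveRefiner(tr$model, path)
  back <- loadRefiner(path)
  expect_identical(refineProbability(back, pre, pm),
                   refineProbability(tr$model, pre, pm))
})

test_that("the CNN hybrids compose end-to-end and enforce the proposal contract", {
  samples <- smallSamples(20, seed = 13, size = 32)
  trK <- trainRefiner(samples, "kmeans", config = refinerConfig(epochs = 3),
                      seed = 5)
  s <- generatePhantom(phantomSpec(width = 32, height = 32, noiseSigma = 15,
                                   illuminationGradient = 0.1, seed = 404))
  res <- kmeansCnnSegment(phantomImage(s), trK$model, seed = 1)
  expect_equal(dim(res$mask), c(32, 32))
  expect_type(res$mask[1, 1], "logical")
  # wrong-proposal model is rejected
  expect_error(fcmCnnSegment(phantomImage(s), trK$model), "fcm")
  # determinism given model + seed
  res2 <- kmeansCnnSegment(phantomImage(s), trK$model, seed = 1)
  expect_identical(res$mask, res2$mask)
  # refinement output only depends on the proposal mask, not cluster ids
  expect_identical(refineMask(trK$model,
                              preprocessImage(phantomImage(s)),
                              res$proposal),
                   res$mask)
})

test_that("a noiseless phantom segments near-perfectly through the CNN path", {
  samples <- smallSamples(24, seed = 15, size = 48, noise = 5, ramp = 0)
  tr <- trainRefiner(samples, "kmeans", config = refinerConfig(epochs = 10),
                     seed = 2)
  s <- twoLevelPhantom(seed = 31, size = 48)
  res <- kmeansCnnSegment(phantomImage(s), tr$model, seed = 1)
  expect_gte(scoreMasks(res$mask, truthMask(s))@dice, 0.99)
})
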