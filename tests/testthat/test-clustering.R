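test_that("fuzzy memberships reproduce hand-evaluated values", {
  expect_equal(fcmMembership(50, c(0, 100), 2)[1, ], c(0.5, 0.5),
               tolerance = 1e-12)
  expect_equal(fcmMembership(0, c(0, 100), 2)[1, ], c(1, 0))
  # pixel 25 between {0,100} at k=2: ratios (25/75)^2 => 1/(1 + 1/9)
  expect_equal(fcmMembership(25, c(0, 100), 2)[1, ], c(0.9, 0.1),
               tolerance = 1e-12)
})

test_that("membership rows always sum to one and duplicate centers are rejected", {
  set.seed(8)
  x <- runif(200, 0, 255)
  for (k in c(1.5, 2, 3)) {
    mu <- fcmMembership(x, c(10, 90, 200), fuzziness = k)
    expect_lt(max(abs(rowSums(mu) - 1)), 1e-9)
    expect_true(all(mu >= 0 & mu <= 1))
  }
  expect_error(fcmMembership(x, c(50, 50)), "degenerate centers")
  expect_error(fcmMembership(x, c(10, 20), fuzziness = 1), "fuzziness")
})

test_that("the FCM objective matches direct evaluation and scales quadratically", {
  # all pixels at their centers
  mu <- fcmMembership(c(0, 100), c(0, 100), 2)
  expect_equal(fcmObjective(c(0, 100), mu, c(0, 100), 2), 0)
  # one pixel at 10, one center at... objective = 1^2 * (10-0)^2
  expect_equal(fcmObjective(10, matrix(1, 1, 1), 0, 2), 100)
  # doubling all distances quadruples the objective at fixed mu
  x <- c(10, 40, 90)
  ctr <- c(0, 100)
  muF <- fcmMembership(x, ctr, 2)
  expect_equal(fcmObjective(2 * x, muF, 2 * ctr, 2),
               4 * fcmObjective(x, muF, ctr, 2), tolerance = 1e-12)
})

test_that("FCM recovers the two levels of a noiseless phantom and emits a faithful mask", {
  s <- twoLevelPhantom(seed = 7)
  part <- fcmSegment(phantomImage(s), nClusters = 2, seed = 3)
  expect_equal(sort(centers(part)), c(40, 200), tolerance = 0.5 / 200)
  expect_lt(max(abs(sort(centers(part)) - c(40, 200))), 0.5)
  mask <- partitionToMask(part)
  expect_gte(scoreMasks(mask, truthMask(s))@dice, 0.99)
  # objective slot is consistent with the returned memberships and centers
  expect_equal(part@objective,
               fcmObjective(phantomImage(s), memberships(part),
                            centers(part), part@fuzziness),
               tolerance = 1e-6)
})

test_that("FCM objective trace is non-increasing and runs are seed-deterministic", {
  s <- generatePhantom(noisyPhantomSpec(size = 64))
  p1 <- fcmSegment(phantomImage(s), seed = 5)
  p2 <- fcmSegment(phantomImage(s), seed = 5)
  expect_identical(memberships(p1), memberships(p2))
  expect_identical(centers(p1), centers(p2))
  tr <- objectiveTrace(p1)
  expect_true(all(diff(tr) <= 1e-6 * pmax(1, tr[-length(tr)])))
})

test_that("degenerate clustering inputs raise informative errors", {
  flat <- matrix(100, 16, 16)
  expect_error(fcmSegment(flat), "single distinct intensity")
  expect_error(kmeansSegment(matrix(c(0, 0, 100, 100), 2, 2), nClusters = 3),
               "degenerate input")
  expect_error(fcmSegment(matrix(1:16, 4, 4), nClusters = 1), "nClusters")
})

test_that("K-means on a two-level phantom equals midpoint thresholding", {
  s <- twoLevelPhantom(seed = 12)
  part <- kmeansSegment(phantomImage(s), seed = 2)
  expect_lt(max(abs(sort(centers(part)) - c(40, 200))), 0.5)
  thresholdMask <- phantomImage(s) > (40 + 200) / 2
  bright <- which.max(centers(part))
  expect_identical(pixelLabels(part) == bright, thresholdMask)
})

test_that("K-means inertia trace is non-increasing and matches the 4-pixel oracle", {
  s <- generatePhantom(noisyPhantomSpec(size = 64))
  part <- kmeansSegment(phantomImage(s), seed = 9)
  tr <- objectiveTrace(part)
  expect_true(all(diff(tr) <= 1e-9 * pmax(1, tr[-length(tr)])))
  p4 <- kmeansSegment(matrix(c(0, 0, 100, 100), 2, 2), seed = 1)
  expect_equal(sort(centers(p4)), c(0, 100))
  expect_equal(p4@inertia, 0)
})

test_that("K-means converges to a Lloyd fixed point on small random instances", {
  set.seed(33)
  for (rep in 1:8) {
    x <- sample(0:255, 10, replace = TRUE)
    if (length(unique(x)) < 2) next
    part <- kmeansSegment(matrix(x, 2, 5), nClusters = 2, seed = rep)
    lab <- as.vector(pixelLabels(part))
    ctr <- centers(part)
    # fixed-point conditions: nearest-center assignment, centers are means
    for (i in seq_along(x))
      expect_equal(lab[i], which.min(abs(x[i] - ctr)))
    for (j in 1:2)
      expect_equal(ctr[j], mean(x[lab == j]), tolerance = 1e-6)
    inertiaOf <- function(lab) {
      sum(vapply(1:2, function(j) {
        m <- x[lab == j]
        if (!length(m)) 0 else sum((m - mean(m))^2)
      }, numeric(1)))
    }
    expect_equal(inertiaOf(lab), part@inertia, tolerance = 1e-9)
  }
})

test_that("mask extraction keeps the largest component, fills holes, and is label-permutation invariant", {
  s <- twoLevelPhantom(seed = 4, size = 64)
  part <- kmeansSegment(phantomImage(s), seed = 1)
  mask <- partitionToMask(part)
  # permute cluster ids: the emitted mask must not change
  perm <- new("HardPartition", labels = 3L - pixelLabels(part),
              centers = rev(centers(part)), inertia = part@inertia,
              inertiaTrace = part@inertiaTrace,
              iterationsRun = part@iterationsRun)
  expect_identical(partitionToMask(perm), mask)
  # fuzzy path: crisp memberships reproduce the blob
  n <- length(phantomImage(s))
  mu <- cbind(as.numeric(truthMask(s)), 1 - as.numeric(truthMask(s)))
  fp <- new("FuzzyPartition", memberships = mu, centers = c(200, 40),
            fuzziness = 2, objective = 0, objectiveTrace = 0,
            iterationsRun = 1L, imageDim = dim(phantomImage(s)))
  expect_identical(partitionToMask(fp), truthMask(s))
  # single-cluster degenerate partition warns about the empty ROI
  lone <- new("HardPartition", labels = matrix(1L, 4, 4), centers = c(9, 200),
              inertia = 0, inertiaTrace = 0, iterationsRun = 1L)
  expect_warning(m0 <- partitionToMask(lone), "empty ROI")
  expect_false(any(m0))
})

test_that("darkest-ROI selection inverts the default rule", {
  s <- generatePhantom(phantomSpec(width = 48, height = 48,
                                   blobIntensityMean = 30,
                                   backgroundIntensityMean = 200,
                                   noiseSigma = 0, illuminationGradient = 0,
                                   seed = 2))
  part <- kmeansSegment(phantomImage(s), seed = 1)
  mask <- partitionToMask(part, selectROI = "darkest")
  expect_gte(scoreMasks(mask, truthMask(s))@dice, 0.99)
})
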