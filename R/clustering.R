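# Traditional clustering segmentation cores. Both FCM and K-means operate on
# per-pixel grayscale intensity (a 1-D feature space). Internally the
# iterations run on the image's distinct intensity values weighted by their
# pixel counts -- algebraically identical to per-pixel updates for 8-bit
# images and far cheaper -- and memberships/labels are expanded back to
# pixels at the end.

# distinct intensity values and their pixel counts
.intensityTable <- function(img) {
  x <- as.vector(img)
  uv <- sort(unique(x))
  cnt <- as.numeric(table(factor(x, levels = uv)))
  list(values = uv, counts = cnt, pixels = x)
}

.checkCenters <- function(centers) {
  if (length(centers) < 2L) stop("at least 2 centers are required")
  if (min(diff(sort(centers))) < 1e-9)
    stop("degenerate centers: cluster centers must be distinct")
}

#' Fuzzy membership matrix
#'
#' The standard FCM membership: for pixel value `x` and centers `C`,
#' `mu_j = 1 / sum_m (|x - C_j| / |x - C_m|)^(2/(k-1))`. Rows sum to 1. A
#' pixel coinciding with a center takes membership 1 there and 0 elsewhere
#' (the hard-assignment limit of the formula, which otherwise divides by
#' zero).
#'
#' @param intensities numeric vector (or image matrix) of pixel values.
#' @param centers distinct cluster center intensities (>= 2).
#' @param fuzziness fuzziness exponent `k` > 1 (default 2).
#' @return numeric matrix, `length(intensities) x length(centers)`.
#' @examples
#' fcmMembership(25, c(0, 100), 2)   # (0.9, 0.1)
#' @export
fcmMembership <- function(intensities, centers, fuzziness = 2) {
  .checkCenters(centers)
  if (fuzziness <= 1) stop("'fuzziness' must be > 1")
  x <- as.vector(intensities)
  d <- abs(outer(x, centers, `-`))
  mu <- matrix(0, length(x), length(centers))
  hit <- d < 1e-12
  atCenter <- rowSums(hit) > 0
  if (any(atCenter)) {
    first <- max.col(-d[atCenter, , drop = FALSE], ties.method = "first")
    mu[cbind(which(atCenter), first)] <- 1
  }
  if (any(!atCenter)) {
    w <- d[!atCenter, , drop = FALSE]^(-2 / (fuzziness - 1))
    mu[!atCenter, ] <- w / rowSums(w)
  }
  mu
}

#' FCM objective (fuzzified within-cluster squared error)
#'
#' `sum_i sum_j mu_ij^k (x_i - C_j)^2`.
#'
#' @inheritParams fcmMembership
#' @param memberships membership matrix as from [fcmMembership()].
#' @return non-negative scalar.
#' @export
fcmObjective <- function(intensities, memberships, centers, fuzziness = 2) {
  x <- as.vector(intensities)
  if (nrow(memberships) != length(x) ||
      ncol(memberships) != length(centers))
    stop("inconsistent shapes between intensities, memberships and centers")
  d2 <- outer(x, centers, `-`)^2
  sum(memberships^fuzziness * d2)
}

# weighted FCM iteration engine starting from given centers
.fcmCore <- function(uv, cnt, centers, fuzziness, tol, maxIter) {
  trace <- numeric(0)
  iter <- 0L
  for (it in seq_len(maxIter)) {
    iter <- it
    mu <- fcmMembership(uv, centers, fuzziness)
    muk <- mu^fuzziness * cnt
    newCenters <- colSums(muk * uv) / colSums(muk)
    # a collapsed (empty-mass) cluster keeps its previous center
    bad <- !is.finite(newCenters)
    newCenters[bad] <- centers[bad]
    d2 <- outer(uv, newCenters, `-`)^2
    trace <- c(trace, sum(muk * d2))
    moved <- max(abs(newCenters - centers))
    centers <- newCenters
    if (moved < tol) break
  }
  # final membership refresh at the converged centers; appending its
  # objective keeps the trace consistent with the returned (mu, centers)
  # pair and cannot break monotonicity (it is the minimizing mu)
  mu <- fcmMembership(uv, centers, fuzziness)
  muk <- mu^fuzziness * cnt
  trace <- c(trace, sum(muk * outer(uv, centers, `-`)^2))
  list(centers = centers, mu = mu, trace = trace, iterations = iter)
}

#' Fuzzy C-means segmentation of a grayscale image
#'
#' Alternates the membership update and the center update
#' `C_j = sum_i mu_ij^k x_i / sum_i mu_ij^k` until the largest center
#' movement falls below `tol` or `maxIter` is reached. Initial centers are
#' distinct pixel intensities drawn from the seeded RNG (weighted by pixel
#' frequency). The objective after each iteration is recorded and is
#' non-increasing.
#'
#' @param img grayscale image matrix in `[0, 255]`.
#' @param nClusters number of clusters (>= 2).
#' @param fuzziness fuzziness exponent > 1 (default 2).
#' @param tol convergence tolerance on center movement (default 1e-4).
#' @param maxIter iteration cap (default 100).
#' @param seed RNG seed for initialization.
#' @param initCenters optional explicit initial centers (overrides the
#'   random draw; used by the swarm hybrids).
#' @return a [FuzzyPartition-class].
#' @export
fcmSegment <- function(img, nClusters = 2, fuzziness = 2, tol = 1e-4,
                       maxIter = 100, seed = 1, initCenters = NULL) {
  checkImage(img)
  if (!is.matrix(img)) stop("'img' must be grayscale")
  if (nClusters < 2) stop("'nClusters' must be >= 2")
  if (maxIter < 1) stop("'maxIter' must be >= 1")
  tab <- .intensityTable(img)
  if (length(tab$values) < 2L)
    stop("degenerate input: image has a single distinct intensity")
  if (nClusters > length(tab$values))
    stop("degenerate input: more clusters requested than distinct intensities")
  centers0 <- if (is.null(initCenters)) {
    withSeed(seed, sample(tab$values, nClusters, prob = tab$counts))
  } else .distinctify(initCenters)
  res <- .fcmCore(tab$values, tab$counts, centers0, fuzziness, tol, maxIter)
  muFull <- res$mu[match(tab$pixels, tab$values), , drop = FALSE]
  new("FuzzyPartition", memberships = muFull, centers = res$centers,
      fuzziness = fuzziness, objective = res$trace[length(res$trace)],
      objectiveTrace = res$trace, iterationsRun = res$iterations,
      imageDim = dim(img))
}

# nudge near-duplicate components apart (swarm positions are penalized for
# duplicates, but guard the refinement path anyway)
.distinctify <- function(centers) {
  centers <- sort(centers)
  for (i in seq_along(centers)[-1])
    if (centers[i] - centers[i - 1] < 1e-9)
      centers[i] <- centers[i - 1] + 1e-6
  centers
}

# weighted Lloyd engine from given centers
.lloydCore <- function(uv, cnt, centers, tol, maxIter) {
  trace <- numeric(0)
  iter <- 0L
  k <- length(centers)
  for (it in seq_len(maxIter)) {
    iter <- it
    d2 <- outer(uv, centers, `-`)^2
    lab <- max.col(-d2, ties.method = "first")
    newCenters <- centers
    for (j in seq_len(k)) {
      m <- lab == j
      if (any(m)) newCenters[j] <- sum(cnt[m] * uv[m]) / sum(cnt[m])
      else {
        # empty cluster: re-seed to the value farthest from its center
        far <- which.max(abs(uv - centers[j]))
        newCenters[j] <- uv[far]
      }
    }
    d2n <- outer(uv, newCenters, `-`)^2
    lab <- max.col(-d2n, ties.method = "first")
    trace <- c(trace, sum(cnt * d2n[cbind(seq_along(uv), lab)]))
    moved <- max(abs(newCenters - centers))
    centers <- newCenters
    if (moved < tol) break
  }
  d2 <- outer(uv, centers, `-`)^2
  lab <- max.col(-d2, ties.method = "first")
  list(centers = centers, labels = lab,
       inertia = sum(cnt * d2[cbind(seq_along(uv), lab)]),
       trace = trace, iterations = iter)
}

#' K-means (Lloyd) segmentation of a grayscale image
#'
#' Lloyd iteration on pixel intensities: assign each pixel to its nearest
#' center, recompute centers as within-cluster means, stop when the largest
#' center movement is below `tol` or at `maxIter`. Empty clusters are
#' re-seeded to the intensity farthest from the vanished center. Initial
#' centers are distinct pixel intensities drawn from the seeded RNG.
#'
#' @inheritParams fcmSegment
#' @return a [HardPartition-class].
#' @export
kmeansSegment <- function(img, nClusters = 2, tol = 1e-4, maxIter = 100,
                          seed = 1, initCenters = NULL) {
  checkImage(img)
  if (!is.matrix(img)) stop("'img' must be grayscale")
  if (nClusters < 2) stop("'nClusters' must be >= 2")
  if (maxIter < 1) stop("'maxIter' must be >= 1")
  tab <- .intensityTable(img)
  if (nClusters > length(tab$values))
    stop("degenerate input: more clusters requested than distinct intensities")
  centers0 <- if (is.null(initCenters)) {
    withSeed(seed, sample(tab$values, nClusters, prob = tab$counts))
  } else .distinctify(initCenters)
  res <- .lloydCore(tab$values, tab$counts, centers0, tol, maxIter)
  labFull <- matrix(res$labels[match(tab$pixels, tab$values)],
                    nrow(img), ncol(img))
  new("HardPartition", labels = labFull, centers = res$centers,
      inertia = res$inertia, inertiaTrace = res$trace,
      iterationsRun = res$iterations)
}

#' Extract the ROI mask from a partition
#'
#' Foreground is the cluster with the highest center intensity (for a fuzzy
#' partition each pixel first takes its argmax-membership cluster); then the
#' largest connected component is retained and its holes filled. The
#' selection rule can be switched to the lowest-intensity cluster for
#' dark-on-bright modalities. The emitted mask is invariant to relabeling of
#' the partition's clusters.
#'
#' @param partition a [FuzzyPartition-class] or [HardPartition-class].
#' @param selectROI `"brightest"` (default) or `"darkest"`.
#' @param postprocess keep the largest connected component and fill holes
#'   (default `TRUE`).
#' @return logical mask matrix of the image's shape.
#' @export
partitionToMask <- function(partition, selectROI = c("brightest", "darkest"),
                            postprocess = TRUE) {
  selectROI <- match.arg(selectROI)
  if (is(partition, "FuzzyPartition")) {
    lab <- matrix(max.col(partition@memberships, ties.method = "first"),
                  partition@imageDim[1], partition@imageDim[2])
    ctr <- partition@centers
  } else if (is(partition, "HardPartition")) {
    lab <- partition@labels
    ctr <- partition@centers
  } else stop("'partition' must be a FuzzyPartition or HardPartition")
  target <- if (selectROI == "brightest") which.max(ctr) else which.min(ctr)
  mask <- lab == target
  if (!any(mask)) {
    warning("empty ROI: no pixel assigned to the selected cluster")
    return(mask)
  }
  if (all(mask) || !postprocess) return(mask)
  cc <- EBImage::bwlabel(EBImage::Image(t(mask) * 1))
  sizes <- table(EBImage::imageData(cc)[EBImage::imageData(cc) > 0])
  keep <- as.integer(names(sizes)[which.max(sizes)])
  largest <- EBImage::Image((EBImage::imageData(cc) == keep) * 1)
  filled <- EBImage::fillHull(largest)
  t(EBImage::imageData(filled)) > 0.5
}
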