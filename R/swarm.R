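# Particle swarm optimization of cluster centers, and the two swarm-hybrid
# segmenters: PSO searches the space of center vectors minimizing the
# clustering objective, then the winning centers seed a final FCM / Lloyd
# refinement.

#' Default PSO hyperparameters
#'
#' Inertia `w = 0.72`, cognitive and social constants `c1 = c2 = 1.49`
#' (constriction-equivalent values), 30 particles, 100 iterations.
#'
#' @param ... overrides (`w`, `c1`, `c2`, `nParticles`, `maxIter`).
#' @return named list.
#' @export
psoHyperparams <- function(...) {
  utils::modifyList(list(w = 0.72, c1 = 1.49, c2 = 1.49, nParticles = 30,
                         maxIter = 100), list(...))
}

#' Clustering fitness of a candidate center vector
#'
#' The quantity a particle minimizes: for `mode = "kmeans"`, the
#' within-cluster sum of squared distances under nearest-center assignment;
#' for `mode = "fcm"`, the fuzzified squared-error objective with
#' memberships computed at the candidate centers. A position with duplicate
#' components (within 1e-9) receives a large finite penalty -- the worst
#' possible objective of the data -- rather than an error, so the swarm can
#' move away from it.
#'
#' @param position candidate center vector.
#' @param intensities pixel intensities (vector or image matrix).
#' @param mode `"kmeans"` or `"fcm"`.
#' @param fuzziness fuzziness exponent for `mode = "fcm"`.
#' @return non-negative scalar; lower is better.
#' @export
clusterFitness <- function(position, intensities, mode = c("kmeans", "fcm"),
                           fuzziness = 2) {
  mode <- match.arg(mode)
  x <- as.vector(intensities)
  .weightedFitness(position, x, rep(1, length(x)), mode, fuzziness)
}

.weightedFitness <- function(position, uv, cnt, mode, fuzziness) {
  if (length(position) > 1 && min(diff(sort(position))) < 1e-9)
    return(sum(cnt) * 255^2)                        # duplicate-center penalty
  d2 <- outer(uv, position, `-`)^2
  if (mode == "kmeans") {
    sum(cnt * d2[cbind(seq_along(uv), max.col(-d2, ties.method = "first"))])
  } else {
    mu <- fcmMembership(uv, position, fuzziness)
    sum(cnt * mu^fuzziness * d2)
  }
}

#' Particle swarm optimization (minimization)
#'
#' Standard PSO update: per component, `V <- w V + c1 r1 (pbest - P) +
#' c2 r2 (gbest - P)`, `P <- P + V`, with `r1`, `r2` fresh uniform(0, 1)
#' draws; positions are clamped to `bounds`, velocities to the bounds range.
#' The global-best fitness trace (one entry for the initial swarm plus one
#' per iteration) is non-increasing by construction.
#'
#' @param fitnessFn function mapping a position vector to a finite scalar.
#' @param dim dimension of the search space.
#' @param bounds numeric `c(lo, hi)` for every component (default intensity
#'   range `c(0, 255)`).
#' @param hyperparams list from [psoHyperparams()].
#' @param seed RNG seed.
#' @param sortPositions sort each position's components after every move
#'   (used by the segmentation hybrids, whose objective is permutation
#'   invariant; removes label-permutation plateaus).
#' @return a [SwarmState-class].
#' @examples
#' st <- psoOptimize(function(p) (p - 7)^2, dim = 1,
#'                   hyperparams = psoHyperparams(nParticles = 10,
#'                                                maxIter = 50), seed = 1)
#' gbestFitness(st)
#' @export
psoOptimize <- function(fitnessFn, dim, bounds = c(0, 255),
                        hyperparams = psoHyperparams(), seed = 1,
                        sortPositions = FALSE) {
  hp <- utils::modifyList(psoHyperparams(), hyperparams)
  n <- hp$nParticles
  if (n < 2) stop("'nParticles' must be >= 2")
  if (hp$maxIter < 1) stop("'maxIter' must be >= 1")
  lo <- bounds[1]; hi <- bounds[2]
  vmax <- hi - lo
  evalAll <- function(P, iter) {
    f <- numeric(nrow(P))
    for (i in seq_len(nrow(P))) {
      f[i] <- fitnessFn(P[i, ])
      if (!is.finite(f[i]))
        stop(sprintf(
          "non-finite fitness for particle %d at iteration %d", i, iter))
    }
    f
  }
  withSeed(seed, {
    P <- matrix(stats::runif(n * dim, lo, hi), n, dim)
    if (sortPositions) P <- t(apply(P, 1, sort))
    if (dim == 1) P <- matrix(P, n, 1)
    V <- matrix(0, n, dim)
    fit <- evalAll(P, 0L)
    pbestP <- P; pbestF <- fit
    g <- which.min(pbestF)
    gbestP <- pbestP[g, ]; gbestF <- pbestF[g]
    trace <- gbestF
    for (t in seq_len(hp$maxIter)) {
      r1 <- matrix(stats::runif(n * dim), n, dim)
      r2 <- matrix(stats::runif(n * dim), n, dim)
      V <- hp$w * V + hp$c1 * r1 * (pbestP - P) +
        hp$c2 * r2 * (matrix(gbestP, n, dim, byrow = TRUE) - P)
      V <- clampRange(V, -vmax, vmax)
      P <- clampRange(P + V, lo, hi)
      if (sortPositions) {
        P <- t(apply(P, 1, sort))
        if (dim == 1) P <- matrix(P, n, 1)
      }
      fit <- evalAll(P, t)
      improved <- fit < pbestF
      pbestP[improved, ] <- P[improved, ]
      pbestF[improved] <- fit[improved]
      g <- which.min(pbestF)
      if (pbestF[g] < gbestF) {
        gbestP <- pbestP[g, ]; gbestF <- pbestF[g]
      }
      trace <- c(trace, gbestF)
    }
    new("SwarmState", positions = P, velocities = V, pbestPositions = pbestP,
        pbestFitness = pbestF, gbestPosition = as.numeric(gbestP),
        gbestFitness = gbestF, gbestTrace = trace,
        iteration = as.integer(hp$maxIter),
        hyperparams = c(hp, list(seed = seed)))
  })
}

# shared front half of the two hybrids: swarm search over center vectors
.psoCenters <- function(img, nClusters, mode, fuzziness, hyperparams, seed) {
  checkImage(img)
  if (!is.matrix(img)) stop("'img' must be grayscale")
  if (nClusters < 2) stop("'nClusters' must be >= 2")
  tab <- .intensityTable(img)
  if (length(tab$values) < 2L)
    stop("degenerate input: image has a single distinct intensity")
  fn <- function(p) .weightedFitness(p, tab$values, tab$counts, mode,
                                     fuzziness)
  state <- psoOptimize(fn, dim = nClusters, bounds = c(0, 255),
                       hyperparams = hyperparams, seed = seed,
                       sortPositions = TRUE)
  list(state = state, tab = tab)
}

#' FCM + PSO hybrid segmentation
#'
#' PSO minimizes the FCM objective over center vectors; the global-best
#' centers then seed a final FCM refinement (whose alternating updates can
#' only lower the objective further), and the refined partition is converted
#' to an ROI mask.
#'
#' @inheritParams fcmSegment
#' @param hyperparams PSO hyperparameters ([psoHyperparams()]).
#' @param selectROI passed to [partitionToMask()].
#' @return list with elements `partition` ([FuzzyPartition-class]), `mask`
#'   (logical matrix), and `swarm` ([SwarmState-class]).
#' @export
fcmPsoSegment <- function(img, nClusters = 2, fuzziness = 2,
                          hyperparams = psoHyperparams(), tol = 1e-4,
                          maxIter = 100, seed = 1,
                          selectROI = "brightest") {
  sw <- .psoCenters(img, nClusters, "fcm", fuzziness, hyperparams, seed)
  part <- fcmSegment(img, nClusters = nClusters, fuzziness = fuzziness,
                     tol = tol, maxIter = maxIter,
                     initCenters = sw$state@gbestPosition)
  list(partition = part,
       mask = partitionToMask(part, selectROI = selectROI),
       swarm = sw$state)
}

#' K-means + PSO hybrid segmentation
#'
#' PSO minimizes the within-cluster sum of squares over center vectors; the
#' global-best centers seed a final Lloyd refinement.
#'
#' @inheritParams fcmPsoSegment
#' @return list with elements `partition` ([HardPartition-class]), `mask`,
#'   and `swarm`.
#' @export
kmeansPsoSegment <- function(img, nClusters = 2,
                             hyperparams = psoHyperparams(), tol = 1e-4,
                             maxIter = 100, seed = 1,
                             selectROI = "brightest") {
  sw <- .psoCenters(img, nClusters, "kmeans", 2, hyperparams, seed)
  part <- kmeansSegment(img, nClusters = nClusters, tol = tol,
                        maxIter = maxIter,
                        initCenters = sw$state@gbestPosition)
  list(partition = part,
       mask = partitionToMask(part, selectROI = selectROI),
       swarm = sw$state)
}
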