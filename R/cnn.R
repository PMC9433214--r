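# Convolutional mask refinement. A small fully-convolutional network maps
# two input channels -- the preprocessed grayscale image (scaled to [0,1])
# and the clustering proposal mask -- to a per-pixel foreground probability.
# Three 3x3 convolutions with dilations 1/2/4 give a 15-pixel receptive
# field at ~1.3k parameters, trained with a Dice + cross-entropy loss under
# Adam. Convolutions are realised as gather (im2col) + matrix products, with
# hand-written backpropagation; no external deep-learning runtime is used.

# cached gather indices for a 3x3 kernel with dilation d on an H x W grid;
# offsets are enumerated (dr, dc) over {-d, 0, d}^2, so block b and block
# 10 - b carry opposite offsets (used to transpose gather into scatter)
.convIdxCache <- new.env(parent = emptyenv())

.convIndices <- function(h, w, d) {
  key <- paste(h, w, d, sep = "x")
  hit <- .convIdxCache[[key]]
  if (!is.null(hit)) return(hit)
  r <- rep(seq_len(h), times = w)
  c <- rep(seq_len(w), each = h)
  idx <- vector("list", 9L)
  b <- 0L
  for (dr in c(-d, 0L, d)) for (dc in c(-d, 0L, d)) {
    b <- b + 1L
    sr <- r + dr; sc <- c + dc
    ok <- sr >= 1L & sr <= h & sc >= 1L & sc <= w
    v <- integer(h * w)
    v[ok] <- sr[ok] + (sc[ok] - 1L) * h
    idx[[b]] <- v
  }
  .convIdxCache[[key]] <- idx
  idx
}

# X: (H*W) x C activation matrix -> (H*W) x 9C patch matrix (zero padding)
.im2col <- function(x, h, w, d) {
  idx <- .convIndices(h, w, d)
  cdim <- ncol(x)
  xp <- rbind(matrix(0, 1L, cdim), x)         # row 1 is the zero pad
  out <- matrix(0, h * w, 9L * cdim)
  for (b in 1:9)
    out[, ((b - 1L) * cdim + 1L):(b * cdim)] <- xp[idx[[b]] + 1L, ,
                                                   drop = FALSE]
  out
}

# transpose of .im2col: scatter patch-gradients back to pixel positions
.col2im <- function(dcol, h, w, d, cdim) {
  idx <- .convIndices(h, w, d)
  dx <- matrix(0, h * w, cdim)
  for (b in 1:9) {
    opp <- idx[[10L - b]]
    blk <- dcol[, ((b - 1L) * cdim + 1L):(b * cdim), drop = FALSE]
    blkp <- rbind(matrix(0, 1L, cdim), blk)
    dx <- dx + blkp[opp + 1L, , drop = FALSE]
  }
  dx
}

.newLayers <- function(hidden, dilations) {
  sizes <- c(2L, hidden, 1L)
  lapply(seq_len(length(sizes) - 1L), function(l) {
    inC <- sizes[l]; outC <- sizes[l + 1L]
    list(W = matrix(stats::rnorm(9L * inC * outC, sd = sqrt(2 / (9 * inC))),
                    9L * inC, outC),
         b = numeric(outC), dilation = dilations[l],
         activation = if (l < length(sizes) - 1L) "relu" else "linear")
  })
}

# forward pass; X is (H*W) x 2. Returns sigmoid probabilities and, when
# training, the per-layer caches needed by backprop.
.refinerForward <- function(layers, x, h, w, keepCache = FALSE) {
  caches <- if (keepCache) vector("list", length(layers)) else NULL
  a <- x
  for (l in seq_along(layers)) {
    ly <- layers[[l]]
    col <- .im2col(a, h, w, ly$dilation)
    z <- col %*% ly$W
    z <- sweep(z, 2, ly$b, `+`)
    a <- if (ly$activation == "relu") pmax(z, 0) else z
    if (keepCache) caches[[l]] <- list(col = col, z = z)
  }
  list(p = 1 / (1 + exp(-a)), caches = caches)
}

# combined loss 0.5 * (1 - softDice) + 0.5 * BCE, with gradient w.r.t. the
# pre-sigmoid logits
.refinerLoss <- function(p, truth) {
  n <- length(truth)
  eps <- 1e-7
  pc <- clampRange(p, eps, 1 - eps)
  bce <- -mean(truth * log(pc) + (1 - truth) * log(1 - pc))
  s <- sum(p * truth); sp <- sum(p); st <- sum(truth)
  smooth <- 1
  dice <- (2 * s + smooth) / (sp + st + smooth)
  loss <- 0.5 * (1 - dice) + 0.5 * bce
  dBce <- (p - truth) / n
  dDice_dp <- (2 * truth * (sp + st + smooth) - (2 * s + smooth)) /
    (sp + st + smooth)^2
  dZ <- 0.5 * dBce + 0.5 * (-dDice_dp) * p * (1 - p)
  list(loss = loss, dZ = matrix(dZ, ncol = 1))
}

.refinerBackward <- function(layers, caches, dz, h, w) {
  grads <- vector("list", length(layers))
  for (l in rev(seq_along(layers))) {
    ly <- layers[[l]]
    col <- caches[[l]]$col
    grads[[l]] <- list(W = crossprod(col, dz), b = colSums(dz))
    if (l > 1L) {
      dcol <- dz %*% t(ly$W)
      dx <- .col2im(dcol, h, w, ly$dilation, nrow(layers[[l]]$W) / 9L)
      zPrev <- caches[[l - 1L]]$z
      dz <- if (layers[[l - 1L]]$activation == "relu")
        dx * (zPrev > 0) else dx
    }
  }
  grads
}

.adamInit <- function(layers)
  lapply(layers, function(ly) list(mW = ly$W * 0, vW = ly$W * 0,
                                   mb = ly$b * 0, vb = ly$b * 0))

.adamStep <- function(layers, grads, state, lr, step,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (l in seq_along(layers)) {
    g <- grads[[l]]; s <- state[[l]]
    s$mW <- b1 * s$mW + (1 - b1) * g$W
    s$vW <- b2 * s$vW + (1 - b2) * g$W^2
    s$mb <- b1 * s$mb + (1 - b1) * g$b
    s$vb <- b2 * s$vb + (1 - b2) * g$b^2
    mHatW <- s$mW / (1 - b1^step); vHatW <- s$vW / (1 - b2^step)
    mHatb <- s$mb / (1 - b1^step); vHatb <- s$vb / (1 - b2^step)
    layers[[l]]$W <- layers[[l]]$W - lr * mHatW / (sqrt(vHatW) + eps)
    layers[[l]]$b <- layers[[l]]$b - lr * mHatb / (sqrt(vHatb) + eps)
    state[[l]] <- s
  }
  list(layers = layers, state = state)
}

.quickDice <- function(pred, truth) {
  tp <- sum(pred & truth)
  den <- 2 * tp + sum(pred & !truth) + sum(!pred & truth)
  if (den == 0) 1 else 2 * tp / den
}

#' Default refiner training configuration
#'
#' @param ... overrides: `epochs` (10), `lr` (0.02), `valFraction` (0.2),
#'   `threshold` (0.5), `hidden` (`c(8, 16)`), `dilations` (`c(1, 2, 4)`),
#'   `enhance` (`TRUE`), `nClusters` (2), `fuzziness` (2),
#'   `checkpointPath` (`NA`).
#' @return named list.
#' @export
refinerConfig <- function(...) {
  utils::modifyList(
    list(epochs = 10, lr = 0.02, valFraction = 0.2, threshold = 0.5,
         hidden = c(8, 16), dilations = c(1, 2, 4), enhance = TRUE,
         nClusters = 2, fuzziness = 2, checkpointPath = NA_character_),
    list(...))
}

#' Train a convolutional mask refiner
#'
#' For every sample the proposal mask is computed by the named clustering
#' method (on the shared preprocessed image), and the network is trained to
#' predict the truth mask from the (image, proposal) pair with a combined
#' Dice + cross-entropy loss. Deterministic given `seed` (and a fixed BLAS
#' thread count).
#'
#' @param samples list of [PhantomSample-class] objects (>= 20), or any list
#'   of `list(image =, truthMask =)` pairs.
#' @param proposalMethod `"kmeans"` or `"fcm"`: which clustering produces
#'   the training proposals.
#' @param config list from [refinerConfig()].
#' @param seed RNG seed covering proposal computation, the train/validation
#'   split, weight initialization and epoch shuffling.
#' @param proposals optional list of precomputed proposal masks (one per
#'   sample), overriding the clustering step.
#' @return list with `model` ([RefinerModel-class]) and `report`
#'   ([TrainReport-class]).
#' @export
trainRefiner <- function(samples, proposalMethod = c("kmeans", "fcm"),
                         config = refinerConfig(), seed = 1,
                         proposals = NULL) {
  proposalMethod <- match.arg(proposalMethod)
  config <- utils::modifyList(refinerConfig(), config)
  n <- length(samples)
  if (n < 20L) stop("at least 20 training samples are required")
  if (config$epochs < 1) stop("'epochs' must be >= 1")

  getImage <- function(s) if (is(s, "PhantomSample")) s@image else s$image
  getTruth <- function(s) if (is(s, "PhantomSample")) s@truthMask else
    s$truthMask

  pre <- lapply(samples, function(s)
    preprocessImage(getImage(s), hairRemoval = "auto",
                    enhance = config$enhance))
  if (is.null(proposals)) {
    proposals <- lapply(seq_len(n), function(i) {
      part <- if (proposalMethod == "kmeans")
        kmeansSegment(pre[[i]], nClusters = config$nClusters,
                      seed = deriveSeed(seed, i))
      else
        fcmSegment(pre[[i]], nClusters = config$nClusters,
                   fuzziness = config$fuzziness, seed = deriveSeed(seed, i))
      suppressWarnings(partitionToMask(part))
    })
  }
  if (!any(vapply(proposals, any, logical(1))))
    stop("training aborted: every proposal mask in the set is empty")

  withSeed(deriveSeed(seed, 777000111), {
    nVal <- max(1L, round(config$valFraction * n))
    valIdx <- sample(n, nVal)
    trainIdx <- setdiff(seq_len(n), valIdx)
    layers <- .newLayers(config$hidden, config$dilations)
    adam <- .adamInit(layers)
    step <- 0L
    lossTrace <- numeric(config$epochs)
    valDice <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample(trainIdx)
      losses <- numeric(length(ord))
      for (k in seq_along(ord)) {
        i <- ord[k]
        h <- nrow(pre[[i]]); w <- ncol(pre[[i]])
        x <- cbind(as.vector(pre[[i]]) / 255,
                   as.numeric(as.vector(proposals[[i]])))
        fw <- .refinerForward(layers, x, h, w, keepCache = TRUE)
        lg <- .refinerLoss(as.vector(fw$p), as.numeric(getTruth(samples[[i]])))
        losses[k] <- lg$loss
        grads <- .refinerBackward(layers, fw$caches, lg$dZ, h, w)
        step <- step + 1L
        upd <- .adamStep(layers, grads, adam, config$lr, step)
        layers <- upd$layers; adam <- upd$state
      }
      lossTrace[ep] <- mean(losses)
      valDice[ep] <- mean(vapply(valIdx, function(i) {
        h <- nrow(pre[[i]]); w <- ncol(pre[[i]])
        x <- cbind(as.vector(pre[[i]]) / 255,
                   as.numeric(as.vector(proposals[[i]])))
        p <- .refinerForward(layers, x, h, w)$p
        .quickDice(matrix(p > config$threshold, h, w), getTruth(samples[[i]]))
      }, numeric(1)))
    }
    model <- new("RefinerModel", layers = layers, config = config,
                 proposalMethod = proposalMethod)
    path <- config$checkpointPath
    if (!is.na(path)) saveRefiner(model, path)
    list(model = model,
         report = new("TrainReport", lossTrace = lossTrace,
                      valDiceTrace = valDice,
                      checkpointPath = as.character(path)))
  })
}

#' Refine a proposal mask with a trained model
#'
#' Runs the network on the (preprocessed grayscale image, proposal) pair and
#' thresholds the probability map. The image must have been preprocessed the
#' same way as the model's training images (see the `enhance` field of the
#' model config). Raising the threshold never grows the foreground set.
#'
#' @param model a [RefinerModel-class].
#' @param img preprocessed grayscale matrix in `[0, 255]`.
#' @param proposal logical proposal mask of the same shape.
#' @param threshold probability cut (default 0.5).
#' @return logical mask of the input shape; warns when empty.
#' @export
refineMask <- function(model, img, proposal, threshold = 0.5) {
  stopifnot(is(model, "RefinerModel"))
  checkImage(img)
  if (!is.matrix(img)) stop("'img' must be grayscale")
  proposal <- asLogicalMask(proposal)
  if (!identical(dim(img), dim(proposal)))
    stop("contract violation: image and proposal shapes differ")
  h <- nrow(img); w <- ncol(img)
  x <- cbind(as.vector(img) / 255, as.numeric(as.vector(proposal)))
  p <- .refinerForward(model@layers, x, h, w)$p
  mask <- matrix(p > threshold, h, w)
  if (!any(mask)) warning("empty ROI: refined mask has no foreground pixel")
  mask
}

#' Probability map of a refiner on one image
#'
#' @inheritParams refineMask
#' @return numeric matrix of per-pixel foreground probabilities in `[0, 1]`.
#' @export
refineProbability <- function(model, img, proposal) {
  stopifnot(is(model, "RefinerModel"))
  h <- nrow(img); w <- ncol(img)
  proposal <- asLogicalMask(proposal)
  x <- cbind(as.vector(img) / 255, as.numeric(as.vector(proposal)))
  matrix(.refinerForward(model@layers, x, h, w)$p, h, w)
}

#' Clustering + CNN hybrid segmentation
#'
#' The full composition: preprocessing, clustering (FCM or K-means), ROI
#' mask extraction, and convolutional refinement. The model's
#' `proposalMethod` must match the clustering used.
#'
#' @param img raw image (matrix or 3-channel array) in `[0, 255]`.
#' @param model a trained [RefinerModel-class].
#' @param nClusters,fuzziness,tol,maxIter,seed clustering settings (see
#'   [fcmSegment()]).
#' @param threshold refinement probability cut.
#' @param selectROI passed to [partitionToMask()].
#' @param hairRemoval passed to [preprocessImage()].
#' @return list with `mask` (refined), `proposal`, and `partition`.
#' @export
fcmCnnSegment <- function(img, model, nClusters = 2, fuzziness = 2,
                          tol = 1e-4, maxIter = 100, seed = 1,
                          threshold = 0.5, selectROI = "brightest",
                          hairRemoval = "auto") {
  stopifnot(is(model, "RefinerModel"))
  if (model@proposalMethod != "fcm")
    stop("model was trained on '", model@proposalMethod,
         "' proposals; an fcm-proposal model is required")
  pre <- preprocessImage(img, hairRemoval = hairRemoval,
                         enhance = model@config$enhance)
  part <- fcmSegment(pre, nClusters = nClusters, fuzziness = fuzziness,
                     tol = tol, maxIter = maxIter, seed = seed)
  proposal <- suppressWarnings(partitionToMask(part, selectROI = selectROI))
  list(mask = refineMask(model, pre, proposal, threshold = threshold),
       proposal = proposal, partition = part)
}

#' @rdname fcmCnnSegment
#' @export
kmeansCnnSegment <- function(img, model, nClusters = 2, tol = 1e-4,
                             maxIter = 100, seed = 1, threshold = 0.5,
                             selectROI = "brightest", hairRemoval = "auto") {
  stopifnot(is(model, "RefinerModel"))
  if (model@proposalMethod != "kmeans")
    stop("model was trained on '", model@proposalMethod,
         "' proposals; a kmeans-proposal model is required")
  pre <- preprocessImage(img, hairRemoval = hairRemoval,
                         enhance = model@config$enhance)
  part <- kmeansSegment(pre, nClusters = nClusters, tol = tol,
                        maxIter = maxIter, seed = seed)
  proposal <- suppressWarnings(partitionToMask(part, selectROI = selectROI))
  list(mask = refineMask(model, pre, proposal, threshold = threshold),
       proposal = proposal, partition = part)
}

#' Save / load a refiner model
#'
#' Round-trips the model so that a reloaded model's forward pass is
#' bit-identical to the in-memory one.
#'
#' @param model a [RefinerModel-class].
#' @param path file path.
#' @return `saveRefiner`: the path, invisibly; `loadRefiner`: the model.
#' @export
saveRefiner <- function(model, path) {
  stopifnot(is(model, "RefinerModel"))
  saveRDS(list(layers = model@layers, config = model@config,
               proposalMethod = model@proposalMethod), path)
  invisible(path)
}

#' @rdname saveRefiner
#' @export
loadRefiner <- function(path) {
  x <- readRDS(path)
  new("RefinerModel", layers = x$layers, config = x$config,
      proposalMethod = x$proposalMethod)
}
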