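#' @import methods
NULL

#' PhantomSpec: parameters of a synthetic phantom image
#'
#' Describes one synthetic 8-bit phantom: bright elliptical blobs on a darker
#' background, corrupted by a linear illumination ramp, Gaussian noise, and
#' optional dark hair-like occluding curves (the dermoscopy artifact).
#'
#' @slot width,height canvas size in pixels (>= 16).
#' @slot nBlobs number of elliptical foreground blobs.
#' @slot blobIntensityMean,backgroundIntensityMean 8-bit intensity levels of
#'   the clean foreground / background; must differ.
#' @slot noiseSigma standard deviation of additive Gaussian noise, in
#'   intensity units.
#' @slot illuminationGradient fractional intensity drop across the frame,
#'   left to right, in `[0, 1]`.
#' @slot hairCount number of dark occluding curves drawn over the image
#'   (never into the truth mask).
#' @slot seed RNG seed; identical spec + seed gives bit-identical output.
#'
#' @seealso [generatePhantom()], [phantomSpec()]
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(width = "integer", height = "integer", nBlobs = "integer",
                 blobIntensityMean = "numeric",
                 backgroundIntensityMean = "numeric",
                 noiseSigma = "numeric", illuminationGradient = "numeric",
                 hairCount = "integer", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@width < 16L)  msg <- c(msg, "width must be >= 16")
  if (object@height < 16L) msg <- c(msg, "height must be >= 16")
  if (object@nBlobs < 1L)  msg <- c(msg, "nBlobs must be >= 1")
  for (f in c("blobIntensityMean", "backgroundIntensityMean")) {
    v <- slot(object, f)
    if (v < 0 || v > 255) msg <- c(msg, sprintf("%s must lie in [0, 255]", f))
  }
  if (object@blobIntensityMean == object@backgroundIntensityMean)
    msg <- c(msg, "blobIntensityMean must differ from backgroundIntensityMean")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (object@illuminationGradient < 0 || object@illuminationGradient > 1)
    msg <- c(msg, "illuminationGradient must lie in [0, 1]")
  if (object@hairCount < 0L) msg <- c(msg, "hairCount must be >= 0")
  if (length(msg)) msg else TRUE
})

#' PhantomSample: a phantom image paired with its exact ground truth
#'
#' @slot image numeric matrix (height x width), intensities in `[0, 255]`.
#' @slot truthMask logical matrix of the same shape marking blob interiors
#'   before any corruption was applied.
#' @slot spec the [PhantomSpec-class] that generated the sample.
#' @exportClass PhantomSample
setClass("PhantomSample",
  representation(image = "matrix", truthMask = "matrix", spec = "PhantomSpec"))

setValidity("PhantomSample", function(object) {
  msg <- character()
  if (!identical(dim(object@image), dim(object@truthMask)))
    msg <- c(msg, "image and truthMask must have identical shape")
  if (!is.logical(object@truthMask))
    msg <- c(msg, "truthMask must be logical")
  else {
    nf <- sum(object@truthMask)
    if (nf == 0L || nf == length(object@truthMask))
      msg <- c(msg, "truthMask must contain both foreground and background")
  }
  if (min(object@image) < 0 || max(object@image) > 255)
    msg <- c(msg, "image intensities must lie in [0, 255]")
  if (length(msg)) msg else TRUE
})

#' FuzzyPartition: the result of fuzzy C-means clustering
#'
#' Holds the membership matrix (one row per pixel in column-major order, one
#' column per cluster), the cluster centers, the fuzziness exponent, and the
#' fuzzified squared-error objective trace.
#'
#' @slot memberships numeric matrix, pixels x clusters, rows summing to 1.
#' @slot centers cluster center intensities.
#' @slot fuzziness fuzziness exponent (> 1); larger is softer.
#' @slot objective final objective (fuzzified within-cluster squared error).
#' @slot objectiveTrace objective after each iteration.
#' @slot iterationsRun iterations executed before convergence.
#' @slot imageDim `c(height, width)` of the clustered image.
#' @exportClass FuzzyPartition
setClass("FuzzyPartition",
  representation(memberships = "matrix", centers = "numeric",
                 fuzziness = "numeric", objective = "numeric",
                 objectiveTrace = "numeric", iterationsRun = "integer",
                 imageDim = "integer"))

setValidity("FuzzyPartition", function(object) {
  msg <- character()
  if (nrow(object@memberships) != prod(object@imageDim))
    msg <- c(msg, "memberships rows must equal prod(imageDim)")
  if (ncol(object@memberships) != length(object@centers))
    msg <- c(msg, "memberships columns must equal length(centers)")
  if (object@fuzziness <= 1)
    msg <- c(msg, "fuzziness must be > 1")
  rs <- rowSums(object@memberships)
  if (max(abs(rs - 1)) > 1e-9)
    msg <- c(msg, "membership rows must sum to 1 (within 1e-9)")
  if (length(msg)) msg else TRUE
})

#' HardPartition: the result of K-means (Lloyd) clustering
#'
#' @slot labels integer matrix (height x width) of cluster indices.
#' @slot centers per-cluster mean intensities.
#' @slot inertia within-cluster sum of squared distances at convergence.
#' @slot inertiaTrace inertia after each Lloyd iteration.
#' @slot iterationsRun iterations executed.
#' @exportClass HardPartition
setClass("HardPartition",
  representation(labels = "matrix", centers = "numeric", inertia = "numeric",
                 inertiaTrace = "numeric", iterationsRun = "integer"))

#' SwarmState: final state of a particle swarm optimization run
#'
#' Particles carry a position (candidate cluster-center vector), a velocity,
#' and their personal best; the swarm tracks the global best and its fitness
#' trace across iterations.
#'
#' @slot positions,velocities,pbestPositions numeric matrices,
#'   particles x dimension.
#' @slot pbestFitness per-particle best fitness.
#' @slot gbestPosition best position visited by any particle.
#' @slot gbestFitness its fitness (minimization).
#' @slot gbestTrace global-best fitness after each iteration (non-increasing).
#' @slot iteration iterations executed.
#' @slot hyperparams list: inertia `w`, cognitive `c1`, social `c2`,
#'   `nParticles`, `maxIter`, `seed`.
#' @exportClass SwarmState
setClass("SwarmState",
  representation(positions = "matrix", velocities = "matrix",
                 pbestPositions = "matrix", pbestFitness = "numeric",
                 gbestPosition = "numeric", gbestFitness = "numeric",
                 gbestTrace = "numeric", iteration = "integer",
                 hyperparams = "list"))

setValidity("SwarmState", function(object) {
  msg <- character()
  if (abs(object@gbestFitness - min(object@pbestFitness)) > 1e-9)
    msg <- c(msg, "gbestFitness must equal the minimum pbest fitness")
  if (length(object@gbestTrace) > 1 &&
      any(diff(object@gbestTrace) > 1e-12))
    msg <- c(msg, "gbestTrace must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' RefinerModel: a small convolutional mask-refinement network
#'
#' A fully-convolutional network taking two input channels -- the
#' preprocessed grayscale image (scaled to `[0, 1]`) and the clustering
#' proposal mask -- and emitting a per-pixel foreground probability.
#'
#' @slot layers list of layer parameter lists (`W`: kernel matrix laid out
#'   as (inChannels x 9) rows, `b`: bias, `dilation`, `activation`).
#' @slot config training configuration (epochs, batchSize is 1 image,
#'   learning rate, seed, validation fraction).
#' @slot proposalMethod which clustering produced the training proposals,
#'   `"fcm"` or `"kmeans"`.
#' @exportClass RefinerModel
setClass("RefinerModel",
  representation(layers = "list", config = "list",
                 proposalMethod = "character"))

#' TrainReport: training diagnostics for a refiner model
#'
#' @slot lossTrace mean training loss per epoch.
#' @slot valDiceTrace validation Dice per epoch (thresholded at 0.5).
#' @slot checkpointPath path of the saved checkpoint, or `NA`.
#' @exportClass TrainReport
setClass("TrainReport",
  representation(lossTrace = "numeric", valDiceTrace = "numeric",
                 checkpointPath = "character"))

setValidity("TrainReport", function(object) {
  if (length(object@lossTrace) == 0 || length(object@valDiceTrace) == 0)
    "lossTrace and valDiceTrace must be non-empty" else TRUE
})

#' MetricReport: the nine-score evaluation of one prediction/truth pair
#'
#' Confusion-count scores (precision, recall, F-measure, accuracy %, error %)
#' and similarity scores (MCC, Dice, Jaccard), plus the wall time of the
#' segmentation call that produced the prediction.
#'
#' @slot precision,recall,fMeasure scalars in `[0, 1]`.
#' @slot accuracyPct,errorPct percentages summing to 100.
#' @slot mcc Matthews correlation coefficient in `[-1, 1]`.
#' @slot dice,jaccard overlap scores; `dice = 2 j / (1 + j)`.
#' @slot elapsedSeconds wall time of segmentation (`NA` when not timed).
#' @exportClass MetricReport
setClass("MetricReport",
  representation(precision = "numeric", recall = "numeric",
                 fMeasure = "numeric", accuracyPct = "numeric",
                 errorPct = "numeric", mcc = "numeric", dice = "numeric",
                 jaccard = "numeric", elapsedSeconds = "numeric"))

setValidity("MetricReport", function(object) {
  msg <- character()
  if (abs(object@accuracyPct + object@errorPct - 100) > 1e-9)
    msg <- c(msg, "accuracyPct + errorPct must equal 100")
  if (abs(object@dice - 2 * object@jaccard / (1 + object@jaccard)) > 1e-9)
    msg <- c(msg, "dice must equal 2*jaccard/(1+jaccard)")
  if (object@mcc < -1 - 1e-12 || object@mcc > 1 + 1e-12)
    msg <- c(msg, "mcc must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' RunConfig: configuration of a benchmark run
#'
#' @slot methods subset of `c("fcm", "kmeans", "fcm-pso", "kmeans-pso",
#'   "fcm-cnn", "kmeans-cnn")`.
#' @slot input list describing the input source: either
#'   `list(type = "dir", imageDir =, truthDir =)` or
#'   `list(type = "phantom", spec = <phantomSpec arguments>, counts =)`.
#' @slot clusterParams,psoParams,cnnParams hyperparameter lists (see
#'   [runBenchmark()] for fields and defaults).
#' @slot seed master seed for the run.
#' @slot outDir output directory.
#' @exportClass RunConfig
setClass("RunConfig",
  representation(methods = "character", input = "list",
                 clusterParams = "list", psoParams = "list",
                 cnnParams = "list", seed = "integer", outDir = "character"))

setValidity("RunConfig", function(object) {
  known <- c("fcm", "kmeans", "fcm-pso", "kmeans-pso", "fcm-cnn", "kmeans-cnn")
  bad <- setdiff(object@methods, known)
  if (length(bad))
    return(sprintf("unknown method(s): %s", paste(bad, collapse = ", ")))
  if (!length(object@methods)) return("at least one method is required")
  if (is.null(object@input$type) ||
      !object@input$type %in% c("dir", "phantom"))
    return("input$type must be 'dir' or 'phantom'")
  TRUE
})
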