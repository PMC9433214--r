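#' Accessors for partition, swarm, and report objects
#'
#' Small accessor generics in the usual Bioconductor style; use these rather
#' than reaching into slots.
#'
#' @param x an object of the documented classes.
#' @return the slot value; see each method.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("centers", function(x) standardGeneric("centers"))

#' @rdname accessors
#' @export
setGeneric("memberships", function(x) standardGeneric("memberships"))

#' @rdname accessors
#' @export
setGeneric("pixelLabels", function(x) standardGeneric("pixelLabels"))

#' @rdname accessors
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))

#' @rdname accessors
#' @export
setGeneric("iterationsRun", function(x) standardGeneric("iterationsRun"))

#' @rdname accessors
#' @export
setGeneric("gbestPosition", function(x) standardGeneric("gbestPosition"))

#' @rdname accessors
#' @export
setGeneric("gbestFitness", function(x) standardGeneric("gbestFitness"))

#' @rdname accessors
#' @export
setGeneric("gbestTrace", function(x) standardGeneric("gbestTrace"))

#' @rdname accessors
#' @export
setGeneric("phantomImage", function(x) standardGeneric("phantomImage"))

#' @rdname accessors
#' @export
setGeneric("truthMask", function(x) standardGeneric("truthMask"))

#' @rdname accessors
#' @export
setGeneric("phantomSpecOf", function(x) standardGeneric("phantomSpecOf"))

#' @rdname accessors
#' @export
setMethod("centers", "FuzzyPartition", function(x) x@centers)
#' @rdname accessors
#' @export
setMethod("centers", "HardPartition", function(x) x@centers)
#' @rdname accessors
#' @export
setMethod("memberships", "FuzzyPartition", function(x) x@memberships)
#' @rdname accessors
#' @export
setMethod("pixelLabels", "HardPartition", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("objectiveTrace", "FuzzyPartition", function(x) x@objectiveTrace)
#' @rdname accessors
#' @export
setMethod("objectiveTrace", "HardPartition", function(x) x@inertiaTrace)
#' @rdname accessors
#' @export
setMethod("iterationsRun", "FuzzyPartition", function(x) x@iterationsRun)
#' @rdname accessors
#' @export
setMethod("iterationsRun", "HardPartition", function(x) x@iterationsRun)
#' @rdname accessors
#' @export
setMethod("gbestPosition", "SwarmState", function(x) x@gbestPosition)
#' @rdname accessors
#' @export
setMethod("gbestFitness", "SwarmState", function(x) x@gbestFitness)
#' @rdname accessors
#' @export
setMethod("gbestTrace", "SwarmState", function(x) x@gbestTrace)
#' @rdname accessors
#' @export
setMethod("phantomImage", "PhantomSample", function(x) x@image)
#' @rdname accessors
#' @export
setMethod("truthMask", "PhantomSample", function(x) x@truthMask)
#' @rdname accessors
#' @export
setMethod("phantomSpecOf", "PhantomSample", function(x) x@spec)

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec %dx%d | %d blob(s) %g on %g | noise %g | ramp %g | %d hair | seed %d\n",
    object@width, object@height, object@nBlobs, object@blobIntensityMean,
    object@backgroundIntensityMean, object@noiseSigma,
    object@illuminationGradient, object@hairCount, object@seed))
})

setMethod("show", "PhantomSample", function(object) {
  d <- dim(object@image)
  cat(sprintf("PhantomSample %dx%d, %d/%d foreground pixels\n",
              d[1], d[2], sum(object@truthMask), length(object@truthMask)))
})

setMethod("show", "FuzzyPartition", function(object) {
  cat(sprintf(
    "FuzzyPartition: %d clusters, centers [%s], fuzziness %g\n  objective %.6g after %d iteration(s)\n",
    length(object@centers),
    paste(sprintf("%.2f", sort(object@centers)), collapse = ", "),
    object@fuzziness, object@objective, object@iterationsRun))
})

setMethod("show", "HardPartition", function(object) {
  cat(sprintf(
    "HardPartition: %d clusters, centers [%s]\n  inertia %.6g after %d iteration(s)\n",
    length(object@centers),
    paste(sprintf("%.2f", sort(object@centers)), collapse = ", "),
    object@inertia, object@iterationsRun))
})

setMethod("show", "SwarmState", function(object) {
  cat(sprintf(
    "SwarmState: %d particles, dim %d, %d iteration(s)\n  gbest [%s], fitness %.6g\n",
    nrow(object@positions), ncol(object@positions), object@iteration,
    paste(sprintf("%.2f", object@gbestPosition), collapse = ", "),
    object@gbestFitness))
})

setMethod("show", "RefinerModel", function(object) {
  np <- sum(vapply(object@layers,
                   function(l) length(l$W) + length(l$b), numeric(1)))
  cat(sprintf(
    "RefinerModel (%s proposals): %d conv layer(s), %d parameters\n",
    object@proposalMethod, length(object@layers), np))
})

setMethod("show", "MetricReport", function(object) {
  cat(sprintf(
    paste0("MetricReport\n  precision %.4f  recall %.4f  F %.4f\n",
           "  accuracy %.4f%%  error %.4f%%\n",
           "  MCC %.4f  Dice %.4f  Jaccard %.4f  time %.3fs\n"),
    object@precision, object@recall, object@fMeasure, object@accuracyPct,
    object@errorPct, object@mcc, object@dice, object@jaccard,
    object@elapsedSeconds))
})

setMethod("show", "RunConfig", function(object) {
  cat(sprintf("RunConfig: methods [%s], input %s, seed %d\n  out: %s\n",
              paste(object@methods, collapse = ", "), object@input$type,
              object@seed, object@outDir))
})

#' Convert a MetricReport (or list of them) to a data.frame
#'
#' @param x a [MetricReport-class].
#' @param row.names,optional ignored (S3 compatibility).
#' @param ... ignored.
#' @return one-row `data.frame` with the nine scores.
#' @export
as.data.frame.MetricReport <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  data.frame(precision = x@precision, recall = x@recall,
             f_measure = x@fMeasure, accuracy_pct = x@accuracyPct,
             error_pct = x@errorPct, mcc = x@mcc, dice = x@dice,
             jaccard = x@jaccard, elapsed_seconds = x@elapsedSeconds)
}

setMethod("as.data.frame", "MetricReport", as.data.frame.MetricReport)
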