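# Evaluation suite: confusion counts, the nine-score report, and
# benchmark-table aggregation.

#' ConfusionCounts: pixelwise confusion table of two binary masks
#'
#' @slot tp,fp,fn,tn non-negative pixel counts; their sum equals the mask's
#'   pixel count.
#' @exportClass ConfusionCounts
setClass("ConfusionCounts",
  representation(tp = "numeric", fp = "numeric", fn = "numeric",
                 tn = "numeric"))

setValidity("ConfusionCounts", function(object) {
  if (any(c(object@tp, object@fp, object@fn, object@tn) < 0))
    "counts must be non-negative" else TRUE
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: tp %g  fp %g  fn %g  tn %g\n",
              object@tp, object@fp, object@fn, object@tn))
})

#' Pixelwise confusion counts
#'
#' Foreground is the positive class.
#'
#' @param pred,truth logical (or 0/1) mask matrices of identical shape.
#' @return a [ConfusionCounts-class].
#' @export
confusionCounts <- function(pred, truth) {
  pred <- asLogicalMask(pred); truth <- asLogicalMask(truth)
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth must have identical shapes")
  new("ConfusionCounts",
      tp = sum(pred & truth), fp = sum(pred & !truth),
      fn = sum(!pred & truth), tn = sum(!pred & !truth))
}

#' Score a confusion table
#'
#' Computes precision, recall, F-measure, accuracy and error (percent), MCC,
#' Dice, and Jaccard. Degenerate 0/0 ratios return 0 by convention (noted
#' via `message()`); a zero MCC denominator likewise yields 0.
#'
#' @param counts a [ConfusionCounts-class] (or the four counts).
#' @param tp,fp,fn,tn alternative scalar interface.
#' @param elapsedSeconds wall time of the segmentation call producing the
#'   prediction (`NA` if untimed); reported, never asserted.
#' @param quiet suppress the 0/0 convention notes.
#' @return a [MetricReport-class].
#' @examples
#' scoreCounts(tp = 1, fp = 1, fn = 1, tn = 1, quiet = TRUE)
#' @export
scoreCounts <- function(counts = NULL, tp = NULL, fp = NULL, fn = NULL,
                        tn = NULL, elapsedSeconds = NA_real_, quiet = FALSE) {
  if (!is.null(counts)) {
    stopifnot(is(counts, "ConfusionCounts"))
    tp <- counts@tp; fp <- counts@fp; fn <- counts@fn; tn <- counts@tn
  }
  if (any(c(tp, fp, fn, tn) < 0)) stop("counts must be non-negative")
  total <- tp + fp + fn + tn
  if (total <= 0) stop("total pixel count must be positive")
  ratio0 <- function(num, den, what) {
    if (den == 0) {
      if (!quiet) message(sprintf("%s is 0/0; returning 0 by convention", what))
      return(0)
    }
    num / den
  }
  precision <- ratio0(tp, tp + fp, "precision")
  recall <- ratio0(tp, tp + fn, "recall")
  fMeasure <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  accuracyPct <- 100 * (tp + tn) / total
  mccDen <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mccDen == 0) 0 else (tp * tn - fp * fn) / mccDen
  dice <- ratio0(2 * tp, 2 * tp + fp + fn, "dice")
  jaccard <- ratio0(tp, tp + fp + fn, "jaccard")
  new("MetricReport", precision = precision, recall = recall,
      fMeasure = fMeasure, accuracyPct = accuracyPct,
      errorPct = 100 - accuracyPct, mcc = mcc, dice = dice,
      jaccard = jaccard, elapsedSeconds = as.numeric(elapsedSeconds))
}

#' Score a prediction mask against ground truth
#'
#' @inheritParams confusionCounts
#' @inheritParams scoreCounts
#' @return a [MetricReport-class].
#' @export
scoreMasks <- function(pred, truth, elapsedSeconds = NA_real_,
                       quiet = TRUE) {
  scoreCounts(confusionCounts(pred, truth),
              elapsedSeconds = elapsedSeconds, quiet = quiet)
}

#' Aggregate per-image metric reports into a benchmark summary
#'
#' Computes per-group arithmetic means of every metric (and elapsed time)
#' from a long-format table of per-image scores, and a wide pivot with
#' methods as columns and groups as rows for each metric -- the layout of an
#' image-count sweep benchmark table.
#'
#' @param reports a `data.frame` with one row per (image, method): the nine
#'   metric columns as produced by `as.data.frame(MetricReport)`, plus
#'   grouping columns (at least `method`).
#' @param groupKeys character vector of grouping column names
#'   (default `c("method", "set_size")`, reduced to those present).
#' @return list with `long` (group means, one row per group) and `pivot`
#'   (one row per metric x non-method group, methods as columns).
#' @export
aggregateReports <- function(reports, groupKeys = c("method", "set_size")) {
  stopifnot(is.data.frame(reports), nrow(reports) > 0)
  groupKeys <- intersect(groupKeys, names(reports))
  if (!length(groupKeys)) stop("no grouping columns found in 'reports'")
  metricCols <- intersect(
    c("precision", "recall", "f_measure", "accuracy_pct", "error_pct",
      "mcc", "dice", "jaccard", "elapsed_seconds"), names(reports))
  agg <- stats::aggregate(reports[metricCols], by = reports[groupKeys],
                          FUN = mean)
  agg <- agg[do.call(order, unname(agg[groupKeys])), , drop = FALSE]
  rownames(agg) <- NULL

  pivot <- NULL
  if ("method" %in% groupKeys) {
    otherKeys <- setdiff(groupKeys, "method")
    rows <- list()
    groups <- if (length(otherKeys))
      unique(agg[, otherKeys, drop = FALSE]) else data.frame(.all = 1)
    for (m in metricCols) {
      for (gi in seq_len(nrow(groups))) {
        sel <- rep(TRUE, nrow(agg))
        for (k in otherKeys) sel <- sel & agg[[k]] == groups[gi, k]
        sub <- agg[sel, , drop = FALSE]
        row <- c(list(metric = m),
                 if (length(otherKeys))
                   as.list(groups[gi, , drop = FALSE]) else NULL,
                 as.list(stats::setNames(sub[[m]], sub$method)))
        rows[[length(rows) + 1L]] <- as.data.frame(row)
      }
    }
    pivot <- do.call(rbind, rows)
    rownames(pivot) <- NULL
  }
  list(long = agg, pivot = pivot)
}
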