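# Benchmark runner: the six-scenario comparison over directories of images
# or generated phantom sets, with per-image metric reports, aggregated
# tables, saved masks, and a reproducibility manifest.

.knownMethods <- c("fcm", "kmeans", "fcm-pso", "kmeans-pso",
                   "fcm-cnn", "kmeans-cnn")

#' Construct a benchmark run configuration
#'
#' @param methods subset of `r paste(.knownMethods, collapse = ", ")`.
#' @param input either `list(type = "phantom", spec = <phantomSpec args>,
#'   counts = <set sizes>)` or `list(type = "dir", imageDir =, truthDir =)`.
#' @param clusterParams list: `nClusters` (2), `fuzziness` (2), `tol`
#'   (1e-4), `maxIter` (100), `selectROI` ("brightest"), `enhance` (TRUE),
#'   `hairRemoval` ("auto").
#' @param psoParams [psoHyperparams()] overrides.
#' @param cnnParams list: either `checkpointFcm` / `checkpointKmeans` paths
#'   to trained models, or `train = TRUE` with `nTrain` (50) and
#'   [refinerConfig()] overrides under `config`.
#' @param seed master seed; every derived seed is a pure function of it.
#' @param outDir output directory.
#' @return a validated [RunConfig-class].
#' @export
runConfig <- function(methods = c("fcm", "kmeans"),
                      input = list(type = "phantom", spec = list(),
                                   counts = 10),
                      clusterParams = list(), psoParams = list(),
                      cnnParams = list(), seed = 1,
                      outDir = tempfile("swarmseg_run_")) {
  new("RunConfig", methods = methods, input = input,
      clusterParams = utils::modifyList(
        list(nClusters = 2, fuzziness = 2, tol = 1e-4, maxIter = 100,
             selectROI = "brightest", enhance = TRUE, hairRemoval = "auto"),
        clusterParams),
      psoParams = do.call(psoHyperparams, psoParams),
      cnnParams = utils::modifyList(
        list(train = FALSE, nTrain = 50, config = list(),
             checkpointFcm = NA_character_,
             checkpointKmeans = NA_character_), cnnParams),
      seed = as.integer(seed), outDir = outDir)
}

.configAsList <- function(config) {
  list(methods = config@methods, input = config@input,
       clusterParams = config@clusterParams, psoParams = config@psoParams,
       cnnParams = config@cnnParams, seed = config@seed,
       outDir = config@outDir)
}

#' Read / write a run configuration as YAML
#'
#' The YAML round trip is lossless: `readRunConfig(writeRunConfig(x))`
#' reproduces the configuration.
#'
#' @param config a [RunConfig-class].
#' @param path YAML file path.
#' @return `writeRunConfig`: the path, invisibly; `readRunConfig`: a
#'   [RunConfig-class].
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(is(config, "RunConfig"))
  yaml::write_yaml(.configAsList(config), path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  x <- yaml::read_yaml(path)
  runConfig(methods = unlist(x$methods), input = x$input,
            clusterParams = x$clusterParams,
            psoParams = x$psoParams[setdiff(names(x$psoParams), "")],
            cnnParams = x$cnnParams, seed = x$seed, outDir = x$outDir)
}

# train (or load) the refiner models the selected methods need
.resolveModels <- function(config) {
  models <- list()
  needs <- c(fcm = "fcm-cnn" %in% config@methods,
             kmeans = "kmeans-cnn" %in% config@methods)
  if (!any(needs)) return(models)
  cp <- config@cnnParams
  for (m in names(needs)[needs]) {
    ckpt <- cp[[if (m == "fcm") "checkpointFcm" else "checkpointKmeans"]]
    if (!is.null(ckpt) && !is.na(ckpt)) {
      if (!file.exists(ckpt))
        stop(sprintf("model checkpoint does not exist: %s", ckpt))
      models[[m]] <- loadRefiner(ckpt)
    } else if (isTRUE(cp$train) || config@input$type == "phantom") {
      spec <- do.call(phantomSpec, as.list(config@input$spec))
      trainSets <- generateBenchmarkSet(spec, counts = cp$nTrain,
                                        seed = deriveSeed(config@seed,
                                                          555000001))
      cfg <- utils::modifyList(
        refinerConfig(enhance = isTRUE(config@clusterParams$enhance),
                      nClusters = config@clusterParams$nClusters,
                      fuzziness = config@clusterParams$fuzziness),
        as.list(cp$config))
      models[[m]] <- trainRefiner(trainSets[[1]], proposalMethod = m,
                                  config = cfg,
                                  seed = deriveSeed(config@seed,
                                                    if (m == "fcm") 31L
                                                    else 37L))$model
    } else {
      stop(sprintf(
        "method %s-cnn needs a checkpoint or cnnParams$train = TRUE", m))
    }
  }
  models
}

# one preprocessed image through one method; returns the mask
.applyMethod <- function(pre, method, config, models, seed) {
  cl <- config@clusterParams
  switch(method,
    "fcm" = partitionToMask(
      fcmSegment(pre, nClusters = cl$nClusters, fuzziness = cl$fuzziness,
                 tol = cl$tol, maxIter = cl$maxIter, seed = seed),
      selectROI = cl$selectROI),
    "kmeans" = partitionToMask(
      kmeansSegment(pre, nClusters = cl$nClusters, tol = cl$tol,
                    maxIter = cl$maxIter, seed = seed),
      selectROI = cl$selectROI),
    "fcm-pso" = fcmPsoSegment(pre, nClusters = cl$nClusters,
                              fuzziness = cl$fuzziness,
                              hyperparams = config@psoParams, tol = cl$tol,
                              maxIter = cl$maxIter, seed = seed,
                              selectROI = cl$selectROI)$mask,
    "kmeans-pso" = kmeansPsoSegment(pre, nClusters = cl$nClusters,
                                    hyperparams = config@psoParams,
                                    tol = cl$tol, maxIter = cl$maxIter,
                                    seed = seed,
                                    selectROI = cl$selectROI)$mask,
    "fcm-cnn" = {
      part <- fcmSegment(pre, nClusters = cl$nClusters,
                         fuzziness = cl$fuzziness, tol = cl$tol,
                         maxIter = cl$maxIter, seed = seed)
      proposal <- suppressWarnings(
        partitionToMask(part, selectROI = cl$selectROI))
      refineMask(models$fcm, pre, proposal)
    },
    "kmeans-cnn" = {
      part <- kmeansSegment(pre, nClusters = cl$nClusters, tol = cl$tol,
                            maxIter = cl$maxIter, seed = seed)
      proposal <- suppressWarnings(
        partitionToMask(part, selectROI = cl$selectROI))
      refineMask(models$kmeans, pre, proposal)
    },
    stop(sprintf("unknown method '%s'", method)))
}

# gather (stem, image, truth, set_size) tuples from the configured input
.collectInputs <- function(config) {
  inp <- config@input
  if (inp$type == "phantom") {
    spec <- do.call(phantomSpec, as.list(inp$spec))
    sets <- generateBenchmarkSet(spec, counts = unlist(inp$counts),
                                 seed = config@seed)
    out <- list()
    for (cn in names(sets))
      for (i in seq_along(sets[[cn]]))
        out[[length(out) + 1L]] <- list(
          stem = sprintf("phantom_%s_%03d", cn, i),
          image = sets[[cn]][[i]]@image,
          truth = sets[[cn]][[i]]@truthMask,
          setSize = as.integer(cn))
    return(out)
  }
  files <- list.files(inp$imageDir,
                      pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                      ignore.case = TRUE)
  files <- files[!grepl("_mask\\.", files)]
  if (!length(files)) stop("no images found in ", inp$imageDir)
  truthDir <- if (!is.null(inp$truthDir)) inp$truthDir else inp$imageDir
  out <- list()
  for (f in sort(files)) {
    stem <- sub("\\.[^.]+$", "", f)
    tpath <- file.path(truthDir, paste0(stem, "_mask.png"))
    if (!file.exists(tpath)) {
      warning(sprintf("no truth mask for %s; image skipped", f))
      next
    }
    out[[length(out) + 1L]] <- list(
      stem = stem,
      image = readImageFile(file.path(inp$imageDir, f)),
      truth = readMaskPNG(tpath),
      setSize = length(files))
  }
  if (!length(out)) stop("no images with truth masks to evaluate")
  out
}

#' Run the segmentation benchmark
#'
#' Loads or generates the configured inputs, runs every selected method on
#' every image behind the shared preprocessing front-end, scores each
#' prediction against its truth mask, and writes per-image masks (PNG), a
#' long-format metrics CSV, an aggregated pivot CSV, and a JSON run manifest
#' (configuration, package version, seed). Fully deterministic given
#' `(config, seed)` except for timestamps and elapsed wall times.
#'
#' @param config a [RunConfig-class] from [runConfig()] /
#'   [readRunConfig()].
#' @param writeMasks write per-image mask PNGs (default `TRUE`).
#' @return list with `reports` (long per-image `data.frame`), `summary`
#'   (per method x set-size means), `pivot` (methods-as-columns table),
#'   `models` (any trained refiners), and `outDir`.
#' @export
runBenchmark <- function(config, writeMasks = TRUE) {
  stopifnot(is(config, "RunConfig"))
  validObject(config)
  dir.create(config@outDir, recursive = TRUE, showWarnings = FALSE)
  maskDir <- file.path(config@outDir, "masks")
  if (writeMasks) dir.create(maskDir, showWarnings = FALSE)

  models <- .resolveModels(config)
  inputs <- .collectInputs(config)
  cl <- config@clusterParams

  rows <- vector("list", length(inputs) * length(config@methods))
  r <- 0L
  for (i in seq_along(inputs)) {
    item <- inputs[[i]]
    pre <- preprocessImage(item$image, hairRemoval = cl$hairRemoval,
                           enhance = isTRUE(cl$enhance))
    segSeed <- deriveSeed(config@seed, 10000L + i)
    for (method in config@methods) {
      elapsed <- system.time(
        mask <- suppressWarnings(
          .applyMethod(pre, method, config, models, segSeed)))[["elapsed"]]
      if (writeMasks)
        writeMaskPNG(mask, file.path(maskDir,
                                     sprintf("%s_%s.png", item$stem, method)))
      rep <- scoreMasks(mask, item$truth, elapsedSeconds = elapsed)
      r <- r + 1L
      rows[[r]] <- cbind(data.frame(image = item$stem, method = method,
                                    set_size = item$setSize),
                         as.data.frame(rep))
    }
  }
  reports <- do.call(rbind, rows[seq_len(r)])
  agg <- aggregateReports(reports)

  writeCsv <- function(df, name) {
    utils::write.csv(df, file.path(config@outDir, name), row.names = FALSE)
  }
  writeCsv(reports, "metrics_long.csv")
  writeCsv(agg$long, "metrics_summary.csv")
  writeCsv(agg$pivot, "metrics_pivot.csv")
  manifest <- list(config = .configAsList(config),
                   package = "SwarmSeg",
                   version = as.character(utils::packageVersion("SwarmSeg")),
                   seed = config@seed,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(config@outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(reports = reports, summary = agg$long, pivot = agg$pivot,
       models = models, outDir = config@outDir)
}

#' Segment a single image file
#'
#' Full path for one image: read, preprocess, segment with the chosen
#' method, optionally score against a truth mask (given explicitly or found
#' as the `<stem>_mask.png` sidecar), and optionally write the mask and a
#' red-overlay visualization.
#'
#' @param imgPath readable PNG/TIFF/JPEG image.
#' @param method one of the six method identifiers.
#' @param config a [RunConfig-class] providing hyperparameters (its input
#'   and methods fields are ignored).
#' @param truthPath optional truth mask PNG; defaults to the sidecar if
#'   present.
#' @param outPath optional mask PNG output path.
#' @param overlayPath optional overlay PNG output path.
#' @param model optional [RefinerModel-class] for `*-cnn` methods
#'   (otherwise the configured checkpoint is loaded).
#' @return list with `mask` and `report` (a [MetricReport-class] or `NULL`
#'   when no truth is available).
#' @export
segmentOne <- function(imgPath, method = "kmeans", config = runConfig(),
                       truthPath = NULL, outPath = NULL, overlayPath = NULL,
                       model = NULL) {
  if (!method %in% .knownMethods)
    stop(sprintf("unknown method '%s'", method))
  img <- readImageFile(imgPath)
  cl <- config@clusterParams
  models <- list()
  if (grepl("-cnn$", method)) {
    key <- sub("-cnn$", "", method)
    if (!is.null(model)) models[[key]] <- model
    else {
      cfg2 <- config
      cfg2@methods <- method
      models <- .resolveModels(cfg2)
    }
  }
  pre <- preprocessImage(img, hairRemoval = cl$hairRemoval,
                         enhance = isTRUE(cl$enhance))
  elapsed <- system.time(
    mask <- suppressWarnings(
      .applyMethod(pre, method, config, models,
                   deriveSeed(config@seed, 1L))))[["elapsed"]]
  if (!is.null(outPath)) writeMaskPNG(mask, outPath)
  if (!is.null(overlayPath)) {
    gray <- toGrayscale(img)
    rgb <- array(rep(gray, 3), c(nrow(gray), ncol(gray), 3))
    red <- rgb[, , 1]; red[mask] <- pmin(255, 0.5 * red[mask] + 127.5)
    g2 <- rgb[, , 2]; g2[mask] <- 0.5 * g2[mask]
    b2 <- rgb[, , 3]; b2[mask] <- 0.5 * b2[mask]
    rgb[, , 1] <- red; rgb[, , 2] <- g2; rgb[, , 3] <- b2
    writeImagePNG(roundHalfUp(rgb), overlayPath)
  }
  report <- NULL
  if (is.null(truthPath)) {
    sidecar <- paste0(sub("\\.[^.]+$", "", imgPath), "_mask.png")
    if (file.exists(sidecar)) truthPath <- sidecar
  }
  if (!is.null(truthPath) && file.exists(truthPath))
    report <- scoreMasks(mask, readMaskPNG(truthPath),
                         elapsedSeconds = elapsed)
  list(mask = mask, report = report)
}
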