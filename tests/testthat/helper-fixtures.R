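# Shared fixtures, all generated in code.

# noiseless two-level phantom with a single blob
twoLevelPhantom <- function(seed = 7, size = 96, fg = 200, bg = 40) {
  generatePhantom(phantomSpec(width = size, height = size,
                              blobIntensityMean = fg,
                              backgroundIntensityMean = bg,
                              noiseSigma = 0, illuminationGradient = 0,
                              hairCount = 0, seed = seed))
}

noisyPhantomSpec <- function(size = 96, noise = 25, ramp = 0.3)
  phantomSpec(width = size, height = size, noiseSigma = noise,
              illuminationGradient = ramp)

# exhaustive 2-cluster K-means oracle: minimum inertia over all 2^n
# nontrivial assignments of n points (centers = cluster means)
bruteForceInertia2 <- function(x) {
  n <- length(x)
  best <- Inf
  for (code in 1:(2^n - 2)) {
    lab <- as.integer(intToBits(code))[1:n]
    i1 <- x[lab == 1L]; i0 <- x[lab == 0L]
    inertia <- sum((i1 - mean(i1))^2) + sum((i0 - mean(i0))^2)
    if (inertia < best) best <- inertia
  }
  best
}

# brute-force per-pixel confusion recount
bruteForceConfusion <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    p <- pred[i, j]; t <- truth[i, j]
    if (p && t) tp <- tp + 1L
    else if (p && !t) fp <- fp + 1L
    else if (!p && t) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

randomMask <- function(h = 16, w = 16) matrix(stats::runif(h * w) > 0.5, h, w)
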