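# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the Mersenne-Twister stream with `seed`, evaluates `expr`, and
#' restores the caller's `.Random.seed`, so library calls never perturb user
#' randomness.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single non-missing number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Round half away from zero; fixes the 8-bit convention used after every
# intensity-valued formula (base round() is banker's rounding).
roundHalfUp <- function(x) floor(x + 0.5)

# Derive a per-sample seed from a master seed and a counter so that set
# membership is independent of iteration order. Stays below 2^31 - 1.
deriveSeed <- function(masterSeed, counter) {
  as.integer((as.numeric(masterSeed) + 1000003 * as.numeric(counter)) %%
               2147483647)
}

# Clamp numeric values into [lo, hi].
clampRange <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Is x an image-like numeric array: H x W matrix (grayscale) or
# H x W x 3 array (color), intensities on the 8-bit scale?
checkImage <- function(x, arg = "img") {
  if (!is.numeric(x) || !(is.matrix(x) || (is.array(x) && length(dim(x)) == 3L)))
    stop(sprintf("'%s' must be a numeric matrix (grayscale) or H x W x 3 array",
                 arg))
  if (is.array(x) && !is.matrix(x) && dim(x)[3] != 3L)
    stop(sprintf("'%s' has %d channels; only 1 or 3 are supported",
                 arg, dim(x)[3]))
  if (anyNA(x)) stop(sprintf("'%s' contains missing values", arg))
  if (min(x) < 0 || max(x) > 255)
    stop(sprintf("'%s' intensities must lie in [0, 255]", arg))
  invisible(TRUE)
}

imageChannels <- function(x) if (is.matrix(x)) 1L else dim(x)[3]

# Binary mask check: logical or 0/1 matrix.
checkMask <- function(x, arg = "mask") {
  if (is.logical(x) && is.matrix(x)) return(invisible(TRUE))
  if (is.numeric(x) && is.matrix(x) && all(x %in% c(0, 1)))
    return(invisible(TRUE))
  stop(sprintf("'%s' must be a logical (or strictly 0/1 numeric) matrix", arg))
}

asLogicalMask <- function(x) {
  checkMask(x)
  if (is.logical(x)) x else x > 0.5
}
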