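# Internal helpers shared across modules.

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
# All stochastic operations in the package are pure functions of
# (input, parameters, seed) via this helper; the generator algorithm is
# whatever RNGkind() reports (recorded in run logs).
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Row-major vectorization shared by every module: pixel (i, j) of an H x W
# image maps to element (i - 1) * W + j of the vector.
vecRowMajor <- function(m) as.vector(t(m))

matRowMajor <- function(v, nrow, ncol) matrix(v, nrow, ncol, byrow = TRUE)

# Coerce CSImage-or-matrix arguments to a plain matrix (grayscale only).
asPixelMatrix <- function(x) {
  if (is(x, "CSImage")) {
    if (nChannels(x) != 1L)
      stop("expected a single-channel image")
    return(x@pixels)
  }
  if (is.matrix(x)) return(x)
  stop("expected a CSImage or a numeric matrix")
}

# Apply fn(channel matrix) -> matrix over each channel of a CSImage,
# returning a CSImage with the same bit depth.
mapChannels <- function(image, fn) {
  px <- pixels(image)
  if (nChannels(image) == 1L) {
    out <- fn(px)
  } else {
    out <- array(0, dim(px))
    for (ch in seq_len(dim(px)[3])) out[, , ch] <- fn(px[, , ch])
  }
  csImage(out, bitDepth(image))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
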