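#' @include AllGenerics.R
NULL

# S4 classes for the imaging pipeline. Images carry intensities as
# unconstrained reals on the native [0, 2^k - 1] scale: clipping to the
# representable range happens only on export, never inside the solver.

#' Image container
#'
#' A `CSImage` holds a grayscale image as a height x width matrix of real
#' intensities, or a colour image as a height x width x 3 array (channels
#' processed independently throughout the package). Intensities live on the
#' native integer scale of the declared bit depth, i.e. `[0, 2^k - 1]`, but
#' are stored as doubles and may leave that range during computation;
#' [writeImageFile()] clips and rounds only at export.
#'
#' @slot pixels numeric matrix (grayscale) or 3-channel array.
#' @slot bitDepth integer, bits per sample (8 or 16 for file I/O).
#'
#' @seealso [csImage()], [readImageFile()], [makePhantom()]
#' @export
setClass("CSImage",
  representation(pixels = "array", bitDepth = "integer"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (!(length(d) == 2L || (length(d) == 3L && d[3] == 3L)))
      return("pixels must be a 2D matrix or a height x width x 3 array")
    if (!all(is.finite(object@pixels)))
      return("all intensities must be finite")
    if (length(object@bitDepth) != 1L || is.na(object@bitDepth) ||
        object@bitDepth < 1L)
      return("bitDepth must be a single positive integer")
    TRUE
  }
)

#' Construct a CSImage
#'
#' @param pixels numeric matrix or height x width x 3 array of intensities on
#'   the `[0, 2^bitDepth - 1]` scale.
#' @param bitDepth integer bits per sample; defaults to 8.
#' @return a [CSImage-class] object.
#' @examples
#' img <- csImage(matrix(128, 16, 16))
#' dynamicRange(img)
#' @export
csImage <- function(pixels, bitDepth = 8L) {
  if (is.matrix(pixels)) storage.mode(pixels) <- "double"
  else pixels <- array(as.double(pixels), dim = dim(pixels))
  new("CSImage", pixels = pixels, bitDepth = as.integer(bitDepth))
}

#' Accessors for CSImage
#'
#' `pixels` returns the raw intensity array, `bitDepth` the declared bits per
#' sample `k`, `dynamicRange` the peak value `2^k - 1`, and `nChannels` 1 or 3.
#'
#' @param x a [CSImage-class].
#' @return see individual descriptions.
#' @name pixels
#' @aliases pixels,CSImage-method
#' @export
setMethod("pixels", "CSImage", function(x) x@pixels)

#' @rdname pixels
#' @export
setMethod("bitDepth", "CSImage", function(x) x@bitDepth)

#' @rdname pixels
#' @export
setMethod("dynamicRange", "CSImage", function(x) 2^x@bitDepth - 1)

#' @rdname pixels
#' @export
setMethod("nChannels", "CSImage", function(x) {
  d <- dim(x@pixels)
  if (length(d) == 2L) 1L else d[3]
})

#' @export
setMethod("dim", "CSImage", function(x) dim(x@pixels))

setMethod("show", "CSImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("CSImage: %d x %d, %d channel(s), %d-bit, range [%.2f, %.2f]\n",
              d[1], d[2], nChannels(object), object@bitDepth,
              min(object@pixels), max(object@pixels)))
})

#' Discrete gradient field
#'
#' The pair of forward finite differences of an image under periodic
#' (circular) boundary conditions. Also used as the container for the
#' split variable `w` and its Lagrange multiplier in the solver.
#'
#' @slot horizontal matrix, differences along columns (wraps at the right edge).
#' @slot vertical matrix, differences along rows (wraps at the bottom edge).
#' @seealso [imageGradient()], [gradientAdjoint()]
#' @export
setClass("GradientField",
  representation(horizontal = "matrix", vertical = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@horizontal), dim(object@vertical)))
      return("horizontal and vertical components must share a shape")
    if (!all(is.finite(object@horizontal)) || !all(is.finite(object@vertical)))
      return("gradient components must be finite")
    TRUE
  }
)

gradientField <- function(horizontal, vertical)
  new("GradientField", horizontal = horizontal, vertical = vertical)

setMethod("show", "GradientField", function(object) {
  d <- dim(object@horizontal)
  cat(sprintf("GradientField: %d x %d components\n", d[1], d[2]))
})

#' Sensing operators
#'
#' A `SensingOperator` is the linear measurement map `A` taking a
#' (row-major vectorized) image of length `N = nCols` to a measurement
#' vector of length `M = nRows`. Concrete kinds:
#' * `IdentitySensingOperator` - `A = I` (pure denoising).
#' * `SubsampledDCTOperator` - `A = R F S`: random +-1 signs `S`, orthonormal
#'   DCT-II `F`, random row selection `R`; rows are exactly orthonormal
#'   (`A A' = I`) and both apply and adjoint cost `O(N log N)`.
#' * `DenseSensingOperator` - an explicit matrix, retained so tiny instances
#'   can be checked against dense linear algebra.
#'
#' @slot nRows integer `M`.
#' @slot nCols integer `N`.
#' @seealso [identityOperator()], [subsampledDCTOperator()], [denseOperator()],
#'   [applyOperator()], [measure()]
#' @export
setClass("SensingOperator",
  representation("VIRTUAL", nRows = "integer", nCols = "integer"),
  validity = function(object) {
    if (object@nRows < 1L || object@nCols < 1L) return("dimensions must be >= 1")
    if (object@nRows > object@nCols) return("requires M <= N")
    TRUE
  }
)

#' @rdname SensingOperator-class
#' @export
setClass("IdentitySensingOperator", contains = "SensingOperator")

#' @rdname SensingOperator-class
#' @slot signs numeric vector of +-1 entries (the diagonal of `S`).
#' @slot rows integer vector of selected DCT rows (the set kept by `R`).
#' @slot seed integer seed the pattern was drawn from.
#' @export
setClass("SubsampledDCTOperator",
  contains = "SensingOperator",
  representation(signs = "numeric", rows = "integer", seed = "integer"),
  validity = function(object) {
    if (length(object@signs) != object@nCols) return("signs must have length N")
    if (length(object@rows) != object@nRows) return("rows must have length M")
    if (any(object@rows < 1L) || any(object@rows > object@nCols) ||
        anyDuplicated(object@rows))
      return("rows must be distinct indices in 1..N")
    if (!all(object@signs %in% c(-1, 1))) return("signs must be +-1")
    TRUE
  }
)

#' @rdname SensingOperator-class
#' @slot mat the explicit M x N matrix.
#' @export
setClass("DenseSensingOperator",
  contains = "SensingOperator",
  representation(mat = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@mat), c(object@nRows, object@nCols)))
      return("matrix dimensions disagree with nRows/nCols")
    TRUE
  }
)

setMethod("show", "SensingOperator", function(object) {
  cat(sprintf("%s: %d x %d\n", class(object), object@nRows, object@nCols))
})

#' Block-matching parameters for the nonlocal self-similarity model
#'
#' Controls how similar patches are grouped: square blocks of side
#' `blockSize`, groups of `groupSize` blocks (reference included) found
#' inside a `searchWindow` x `searchWindow` window centred on the reference
#' block, reference blocks taken on a stride-`step` grid (overlapping for
#' `step < blockSize`). `transform` selects the separable orthonormal 3D
#' transform applied to each group; `thresholdScale` multiplies the
#' coefficient shrinkage threshold (see the methods vignette).
#'
#' @slot blockSize integer block side (pixels), >= 2.
#' @slot groupSize integer blocks per group, >= 1.
#' @slot searchWindow integer search-window side (pixels), >= blockSize.
#' @slot step integer reference-block stride, >= 1.
#' @slot transform `"dct3d"` (DCT-II along all three axes) or
#'   `"dct2d_haar1d"` (2D DCT within blocks, Haar across the group).
#' @slot thresholdScale numeric multiplier on the shrinkage threshold.
#' @seealso [nlsParams()], [findSimilarBlocks()], [solveXSubproblem()]
#' @export
setClass("NLSParams",
  representation(blockSize = "integer", groupSize = "integer",
                 searchWindow = "integer", step = "integer",
                 transform = "character", thresholdScale = "numeric"),
  validity = function(object) {
    if (object@blockSize < 2L) return("blockSize must be >= 2")
    if (object@groupSize < 1L) return("groupSize must be >= 1")
    if (object@searchWindow < object@blockSize)
      return("searchWindow must be >= blockSize")
    if (object@step < 1L) return("step must be >= 1")
    if (!object@transform %in% c("dct3d", "dct2d_haar1d"))
      return("transform must be 'dct3d' or 'dct2d_haar1d'")
    if (object@transform == "dct2d_haar1d" &&
        bitwAnd(object@groupSize, object@groupSize - 1L) != 0L)
      return("dct2d_haar1d requires groupSize to be a power of two")
    if (object@thresholdScale < 0) return("thresholdScale must be >= 0")
    TRUE
  }
)

#' @rdname NLSParams-class
#' @param blockSize,groupSize,searchWindow,step,transform,thresholdScale see slots.
#' @return an `NLSParams` object.
#' @examples
#' nlsParams(blockSize = 4, groupSize = 8, searchWindow = 15)
#' @export
nlsParams <- function(blockSize = 8L, groupSize = 16L, searchWindow = 39L,
                      step = max(1L, as.integer(blockSize) %/% 2L),
                      transform = c("dct3d", "dct2d_haar1d"),
                      thresholdScale = 2) {
  transform <- match.arg(transform)
  new("NLSParams", blockSize = as.integer(blockSize),
      groupSize = as.integer(groupSize),
      searchWindow = as.integer(searchWindow), step = as.integer(step),
      transform = transform, thresholdScale = thresholdScale)
}

setMethod("show", "NLSParams", function(object) {
  cat(sprintf(
    "NLSParams: %dx%d blocks, groups of %d, window %d, step %d, %s (c=%g)\n",
    object@blockSize, object@blockSize, object@groupSize,
    object@searchWindow, object@step, object@transform,
    object@thresholdScale))
})

#' A group of mutually similar image blocks
#'
#' The reference block plus its `groupSize - 1` nearest neighbours (squared
#' Euclidean patch distance) stacked into an n x n x m array. Member 1 is
#' always the reference; distances are nondecreasing along the member order,
#' ties broken by row-major scan order of the candidate positions.
#'
#' @slot referenceIndex integer (row, col) of the reference block's top-left.
#' @slot memberIndices m x 2 integer matrix of member top-left positions.
#' @slot distances numeric vector of squared distances to the reference.
#' @slot stack n x n x m numeric array of the member blocks.
#' @seealso [findSimilarBlocks()]
#' @export
setClass("BlockGroup",
  representation(referenceIndex = "integer", memberIndices = "matrix",
                 distances = "numeric", stack = "array"),
  validity = function(object) {
    m <- dim(object@stack)[3]
    if (nrow(object@memberIndices) != m || length(object@distances) != m)
      return("member count must match the stack depth")
    if (!identical(object@memberIndices[1, ], object@referenceIndex))
      return("member 1 must be the reference block")
    if (is.unsorted(object@distances)) return("distances must be nondecreasing")
    TRUE
  }
)

setMethod("show", "BlockGroup", function(object) {
  d <- dim(object@stack)
  cat(sprintf("BlockGroup: %d blocks of %dx%d, reference at (%d, %d)\n",
              d[3], d[1], d[2],
              object@referenceIndex[1], object@referenceIndex[2]))
})

#' Transform coefficients of a block group
#'
#' The separable orthonormal 3D transform of a [BlockGroup-class] stack.
#' The inverse transform recovers the stack exactly (to numerical precision)
#' when no thresholding is applied.
#'
#' @slot coefficients n x n x m numeric array.
#' @slot transform the transform id (`"dct3d"` or `"dct2d_haar1d"`).
#' @seealso [groupTransform()], [groupInverseTransform()]
#' @export
setClass("CoefficientStack",
  representation(coefficients = "array", transform = "character"))

setMethod("show", "CoefficientStack", function(object) {
  d <- dim(object@coefficients)
  cat(sprintf("CoefficientStack (%s): %d x %d x %d\n",
              object@transform, d[1], d[2], d[3]))
})

#' Noise model specification
#'
#' Describes the corruption applied to a clean image: additive white Gaussian
#' noise of standard deviation `sigma` and mean `mean` (intensity units), or
#' salt-and-pepper noise setting each pixel independently to `vMax` with
#' probability `q1` and `vMin` with probability `q2` (total level
#' `q = q1 + q2`).
#'
#' @slot kind `"awgn"` or `"salt_pepper"`.
#' @slot sigma,mean AWGN parameters (intensity units).
#' @slot q1,q2 salt and pepper probabilities; `q1 + q2 <= 1`.
#' @slot vMax,vMin salt/pepper intensities (`NA` means the image's dynamic
#'   range maximum and 0).
#' @seealso [noiseSpec()], [applyNoise()]
#' @export
setClass("NoiseSpec",
  representation(kind = "character", sigma = "numeric", mean = "numeric",
                 q1 = "numeric", q2 = "numeric", vMax = "numeric",
                 vMin = "numeric"),
  validity = function(object) {
    if (!object@kind %in% c("awgn", "salt_pepper"))
      return("kind must be 'awgn' or 'salt_pepper'")
    if (object@sigma < 0) return("sigma must be >= 0")
    if (object@q1 < 0 || object@q2 < 0 || object@q1 + object@q2 > 1)
      return("need q1, q2 >= 0 and q1 + q2 <= 1")
    TRUE
  }
)

#' @rdname NoiseSpec-class
#' @param kind,sigma,mean,q1,q2,vMax,vMin see slots. For salt-and-pepper a
#'   total level `q` may be given instead of `q1`/`q2`; it is split evenly.
#' @param q optional total salt-and-pepper level.
#' @return a `NoiseSpec`.
#' @examples
#' noiseSpec("awgn", sigma = 20)
#' noiseSpec("salt_pepper", q = 0.2)
#' @export
noiseSpec <- function(kind = c("awgn", "salt_pepper"), sigma = 0, mean = 0,
                      q = NULL, q1 = NULL, q2 = NULL, vMax = NA_real_,
                      vMin = 0) {
  kind <- match.arg(kind)
  if (is.null(q1) && is.null(q2)) {
    if (is.null(q)) q <- 0
    q1 <- q / 2; q2 <- q / 2
  } else {
    if (is.null(q1)) q1 <- 0
    if (is.null(q2)) q2 <- 0
  }
  new("NoiseSpec", kind = kind, sigma = sigma, mean = mean,
      q1 = q1, q2 = q2, vMax = vMax, vMin = vMin)
}

setMethod("show", "NoiseSpec", function(object) {
  if (object@kind == "awgn")
    cat(sprintf("NoiseSpec: AWGN sigma=%g mean=%g\n", object@sigma, object@mean))
  else
    cat(sprintf("NoiseSpec: salt & pepper q1=%g q2=%g\n", object@q1, object@q2))
})
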