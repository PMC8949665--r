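# Sensing operators: the measurement map f = A u as matched apply/adjoint
# contracts. Row-major vectorization is shared by every module.

#' Identity sensing operator
#'
#' The pure-denoising case: `A = I`, `M = N`.
#'
#' @param n signal length (pixel count), >= 1.
#' @return an `IdentitySensingOperator`.
#' @export
identityOperator <- function(n) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  new("IdentitySensingOperator", nRows = n, nCols = n)
}

#' Subsampled orthonormal DCT sensing operator
#'
#' Builds `A = R F S`: a random diagonal sign flip `S`, the orthonormal
#' DCT-II `F`, and a uniformly random selection `R` of `mRows` of its rows.
#' The rows of `A` are exactly orthonormal (`A A' = I` on R^M), applications
#' cost `O(N log N)`, and the operator is reconstructed bit-identically from
#' `(n, mRows, seed)`.
#'
#' @param n signal length `N`.
#' @param mRows number of measurements `M`, `1 <= M <= N`.
#' @param seed integer seed for the sign pattern and row set.
#' @return a `SubsampledDCTOperator`.
#' @examples
#' op <- subsampledDCTOperator(64, 32, seed = 1)
#' u <- rnorm(64)
#' length(applyOperator(op, u))
#' @export
subsampledDCTOperator <- function(n, mRows, seed = 0L) {
  n <- as.integer(n); mRows <- as.integer(mRows)
  if (mRows < 1L || mRows > n) stop("need 1 <= mRows <= n")
  withSeed(seed, {
    signs <- sample(c(-1, 1), n, replace = TRUE)
    rows <- sort(sample.int(n, mRows))
    new("SubsampledDCTOperator", nRows = mRows, nCols = n,
        signs = signs, rows = rows, seed = as.integer(seed))
  })
}

#' Explicit-matrix sensing operator
#'
#' Wraps a dense M x N matrix, for tiny instances where the whole pipeline
#' can be cross-checked against dense linear algebra.
#'
#' @param mat numeric matrix with `nrow(mat) <= ncol(mat)`.
#' @return a `DenseSensingOperator`.
#' @export
denseOperator <- function(mat) {
  new("DenseSensingOperator", nRows = nrow(mat), nCols = ncol(mat), mat = mat)
}

#' @rdname applyOperator
setMethod("applyOperator", "IdentitySensingOperator", function(op, v) {
  stopifnot(length(v) == op@nCols)
  v
})

#' @rdname applyOperator
setMethod("adjointOperator", "IdentitySensingOperator", function(op, v) {
  stopifnot(length(v) == op@nRows)
  v
})

#' @rdname applyOperator
setMethod("applyOperator", "SubsampledDCTOperator", function(op, v) {
  stopifnot(length(v) == op@nCols)
  dctOrtho(op@signs * v)[op@rows]
})

#' @rdname applyOperator
setMethod("adjointOperator", "SubsampledDCTOperator", function(op, v) {
  stopifnot(length(v) == op@nRows)
  full <- numeric(op@nCols)
  full[op@rows] <- v
  op@signs * idctOrtho(full)
})

#' @rdname applyOperator
setMethod("applyOperator", "DenseSensingOperator", function(op, v) {
  stopifnot(length(v) == op@nCols)
  as.vector(op@mat %*% v)
})

#' @rdname applyOperator
setMethod("adjointOperator", "DenseSensingOperator", function(op, v) {
  stopifnot(length(v) == op@nRows)
  as.vector(crossprod(op@mat, v))
})

#' @rdname operatorSpec
setMethod("operatorSpec", "IdentitySensingOperator", function(op)
  list(kind = "identity", n = op@nCols))

#' @rdname operatorSpec
setMethod("operatorSpec", "SubsampledDCTOperator", function(op)
  list(kind = "subsampled_dct", n = op@nCols, mRows = op@nRows,
       seed = op@seed, rows = op@rows))

#' @rdname operatorSpec
setMethod("operatorSpec", "DenseSensingOperator", function(op)
  list(kind = "explicit_matrix", n = op@nCols, mRows = op@nRows,
       mat = op@mat))

#' Rebuild a sensing operator from its serialized spec
#'
#' @param spec a list as produced by [operatorSpec()] (or read back from a
#'   YAML/JSON config).
#' @return a [SensingOperator-class].
#' @export
operatorFromSpec <- function(spec) {
  switch(spec$kind,
    identity = identityOperator(spec$n),
    subsampled_dct = subsampledDCTOperator(spec$n, spec$mRows, spec$seed),
    explicit_matrix = denseOperator(
      if (is.matrix(spec$mat)) spec$mat
      else matrix(unlist(spec$mat), nrow = spec$mRows, byrow = TRUE)),
    stop("unknown operator kind: ", spec$kind)
  )
}

#' Measure an image through a sensing operator
#'
#' Computes `A vec(image)` with row-major vectorization.
#'
#' @param op a [SensingOperator-class] with `nCols` equal to the pixel count.
#' @param image a single-channel [CSImage-class] or matrix.
#' @return the measurement vector of length `nRows(op)`.
#' @export
measure <- function(op, image) {
  px <- asPixelMatrix(image)
  if (op@nCols != length(px))
    stop("operator expects ", op@nCols, " pixels, image has ", length(px))
  applyOperator(op, vecRowMajor(px))
}
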