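# Nonlocal self-similarity: block matching, the separable orthonormal 3D
# group transform, the NLS functional, the coefficient-shrinkage x-update,
# and the aggregation operator that averages overlapping blocks back into
# an image.

# Orthonormal full-depth Haar matrix, m a power of two.
haarMatrix <- function(m) {
  if (m == 1L) return(matrix(1, 1, 1))
  if (bitwAnd(m, m - 1L) != 0L) stop("Haar transform needs a power-of-two size")
  Hprev <- haarMatrix(m %/% 2L)
  top <- Hprev %x% matrix(c(1, 1) / sqrt(2), 1, 2)
  bottom <- diag(m %/% 2L) %x% matrix(c(1, -1) / sqrt(2), 1, 2)
  rbind(top, bottom)
}

# Transform matrix along the similarity axis.
similarityAxisMatrix <- function(params) {
  if (params@transform == "dct3d") dctMatrix(params@groupSize)
  else haarMatrix(params@groupSize)
}

# Reference-block grid along one dimension: stride `step`, with the final
# position appended so blocks cover the image edge. 1-based.
referenceGrid <- function(extent, blockSize, step) {
  last <- extent - blockSize + 1L
  if (last < 1L) stop("image smaller than the block size")
  g <- seq.int(1L, last, by = step)
  if (g[length(g)] != last) g <- c(g, last)
  as.integer(g)
}

#' Find the blocks most similar to a reference block
#'
#' Candidates are all blocks fully inside both the image and the
#' `searchWindow` x `searchWindow` window centred on the reference block;
#' similarity is squared Euclidean distance on raw intensities. Returns the
#' reference (always member 1, distance 0) plus the `groupSize - 1` nearest
#' candidates, ties broken by row-major candidate order.
#'
#' @param image single-channel [CSImage-class] or matrix.
#' @param ref integer `(row, col)` of the reference block's top-left corner
#'   (1-based).
#' @param params an [NLSParams-class].
#' @return a [BlockGroup-class].
#' @examples
#' img <- makePhantom(64, 64, seed = 1)
#' g <- findSimilarBlocks(img, c(40, 8), nlsParams(blockSize = 8,
#'   groupSize = 8, searchWindow = 21))
#' g@distances
#' @export
findSimilarBlocks <- function(image, ref, params) {
  px <- asPixelMatrix(image)
  n <- params@blockSize
  if (ref[1] < 1L || ref[2] < 1L || ref[1] + n - 1L > nrow(px) ||
      ref[2] + n - 1L > ncol(px))
    stop("reference block falls outside the image")
  res <- .cppMatchBlocks(px, as.integer(ref[1]) - 1L, as.integer(ref[2]) - 1L,
                         n, params@groupSize, params@searchWindow)
  idx <- res$indices + 1L
  m <- nrow(idx)
  stack <- array(0, c(n, n, m))
  for (k in seq_len(m))
    stack[, , k] <- px[idx[k, 1]:(idx[k, 1] + n - 1L),
                       idx[k, 2]:(idx[k, 2] + n - 1L)]
  new("BlockGroup", referenceIndex = as.integer(ref),
      memberIndices = idx, distances = res$distances, stack = stack)
}

# Separable orthonormal 3D transform of a stack (n x n x m array).
stackTransform <- function(stack, Tn, Tm, inverse = FALSE) {
  d <- dim(stack)
  n <- d[1]; m <- d[3]
  An <- if (inverse) t(Tn) else Tn
  Am <- if (inverse) t(Tm) else Tm
  out <- array(0, d)
  for (k in seq_len(m)) out[, , k] <- An %*% stack[, , k] %*% t(An)
  matrix(out, n * n, m) %*% t(Am) -> flat
  array(flat, d)
}

#' Orthonormal 3D transform of a block group
#'
#' Applies the separable orthonormal transform (DCT-II along rows, columns
#' and the similarity axis by default; optionally Haar along the similarity
#' axis) to the group's stack. Orthonormality gives exact energy
#' conservation per group, which is what makes the coefficient-domain
#' shrinkage threshold meaningful.
#'
#' @param group a [BlockGroup-class].
#' @param params an [NLSParams-class].
#' @return a [CoefficientStack-class].
#' @export
groupTransform <- function(group, params) {
  Tn <- dctMatrix(params@blockSize)
  Tm <- similarityAxisMatrix(params)
  new("CoefficientStack",
      coefficients = stackTransform(group@stack, Tn, Tm),
      transform = params@transform)
}

#' @rdname groupTransform
#' @param coeffs a [CoefficientStack-class].
#' @return for `groupInverseTransform`, the reconstructed n x n x m array.
#' @export
groupInverseTransform <- function(coeffs, params) {
  Tn <- dctMatrix(params@blockSize)
  Tm <- similarityAxisMatrix(params)
  stackTransform(coeffs@coefficients, Tn, Tm, inverse = TRUE)
}

#' Nonlocal self-similarity functional
#'
#' The sum, over reference blocks on the stride grid, of the l1 norm of each
#' group's 3D transform coefficients.
#'
#' @param image single-channel [CSImage-class] or matrix.
#' @param params an [NLSParams-class].
#' @return a scalar.
#' @export
nlsNorm <- function(image, params) {
  px <- asPixelMatrix(image)
  gr <- referenceGrid(nrow(px), params@blockSize, params@step)
  gc <- referenceGrid(ncol(px), params@blockSize, params@step)
  Tn <- dctMatrix(params@blockSize)
  Tm <- similarityAxisMatrix(params)
  res <- .cppGroupShrinkPass(px, gr - 1L, gc - 1L, params@blockSize,
                             params@groupSize, params@searchWindow,
                             Tn, Tm, 0, px)
  res$l1_before
}

#' Aggregate processed blocks back into an image
#'
#' The reconstruction operator: scatter every block of every group back to
#' its position, sum the contributions, and divide each pixel by its
#' coverage count (uniform weights). Pixels covered by no block take the
#' value of `fallback`.
#'
#' @param stacks list of n x n x m arrays (processed groups).
#' @param positions list of m x 2 integer matrices of member top-left
#'   positions (1-based), parallel to `stacks`.
#' @param shape integer `(height, width)` of the output.
#' @param fallback matrix of pass-through values for uncovered pixels
#'   (default zeros).
#' @return a matrix of shape `shape`.
#' @export
aggregateBlocks <- function(stacks, positions, shape,
                            fallback = matrix(0, shape[1], shape[2])) {
  acc <- matrix(0, shape[1], shape[2])
  cov <- matrix(0, shape[1], shape[2])
  for (g in seq_along(stacks)) {
    st <- stacks[[g]]; pos <- positions[[g]]
    n <- dim(st)[1]
    for (k in seq_len(dim(st)[3])) {
      ri <- pos[k, 1]:(pos[k, 1] + n - 1L)
      ci <- pos[k, 2]:(pos[k, 2] + n - 1L)
      acc[ri, ci] <- acc[ri, ci] + st[, , k]
      cov[ri, ci] <- cov[ri, ci] + 1
    }
  }
  out <- fallback
  covered <- cov > 0
  out[covered] <- acc[covered] / cov[covered]
  out
}

#' Nonlocal shrinkage update (x-subproblem)
#'
#' Solves the self-similarity subproblem of the alternating scheme:
#' minimizes `lambdaNLS ||theta(x)||_1 - <phi, u - x> + rhoNLS/2 ||u - x||^2`
#' approximately by collaborative shrinkage. Forms the proxy observation
#' r given by `u - phi / rhoNLS`; for each reference-block group of r, applies
#' the orthonormal 3D transform, soft-thresholds every coefficient at
#' `thr = c K lambdaNLS / (N rhoNLS)` with `K = n^2 m` the per-group
#' coefficient count, `N` the image pixel count and `c` the threshold scale
#' from `params`; inverse-transforms; and aggregates overlapping blocks by
#' coverage-weighted averaging. Uncovered pixels (none, with the default
#' edge-completing grid) pass through from `r`.
#'
#' @param u current image iterate (matrix or single-channel [CSImage-class]).
#' @param phi Lagrange multiplier (matrix of the same shape, or 0).
#' @param lambdaNLS self-similarity weight, >= 0.
#' @param rhoNLS penalty parameter, > 0.
#' @param params an [NLSParams-class].
#' @param matchOn optional image (matrix or [CSImage-class]) on which block
#'   matching is performed instead of `r` itself; fixing the matching to the
#'   initial observation keeps the group structure constant across solver
#'   iterations.
#' @return the updated image as a matrix.
#' @export
solveXSubproblem <- function(u, phi, lambdaNLS, rhoNLS, params,
                             matchOn = NULL) {
  if (rhoNLS <= 0) stop("rhoNLS must be > 0")
  if (lambdaNLS < 0) stop("lambdaNLS must be >= 0")
  px <- asPixelMatrix(u)
  if (is.numeric(phi) && length(phi) == 1L) phi <- matrix(phi, nrow(px), ncol(px))
  r <- px - phi / rhoNLS
  n <- params@blockSize; m <- params@groupSize
  K <- n * n * m
  N <- length(r)
  thr <- params@thresholdScale * K * lambdaNLS / (N * rhoNLS)
  gr <- referenceGrid(nrow(r), n, params@step)
  gc <- referenceGrid(ncol(r), n, params@step)
  Tn <- dctMatrix(n)
  Tm <- similarityAxisMatrix(params)
  matchImg <- if (is.null(matchOn)) r else asPixelMatrix(matchOn)
  res <- .cppGroupShrinkPass(r, gr - 1L, gc - 1L, n, m, params@searchWindow,
                             Tn, Tm, thr, matchImg)
  out <- r
  covered <- res$cov > 0
  out[covered] <- res$acc[covered] / res$cov[covered]
  attr(out, "l1Before") <- res$l1_before
  attr(out, "l1After") <- res$l1_after
  out
}
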