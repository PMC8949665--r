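# Total-variation machinery: periodic forward differences, their exact
# adjoint, the TV functional, and the closed-form shrinkage step for the
# gradient split variable.

#' Discrete image gradient (periodic forward differences)
#'
#' `(Dh u)[i, j] = u[i, j+1 mod W] - u[i, j]` and analogously along rows.
#' The circular boundary makes `D'D` the periodic 5-point Laplacian,
#' diagonal in the 2D Fourier basis, which the solver's spectral u-update
#' exploits.
#'
#' @param u image matrix or single-channel [CSImage-class].
#' @return a [GradientField-class].
#' @export
imageGradient <- function(u) {
  u <- asPixelMatrix(u)
  W <- ncol(u); H <- nrow(u)
  gradientField(horizontal = u[, c(2:W, 1), drop = FALSE] - u,
                vertical   = u[c(2:H, 1), , drop = FALSE] - u)
}

#' Adjoint of the discrete gradient
#'
#' The exact adjoint of [imageGradient()] under the Euclidean inner product
#' (the negative periodic divergence): `<D u, p> == <u, D' p>` to machine
#' precision.
#'
#' @param p a [GradientField-class].
#' @return an image matrix.
#' @export
gradientAdjoint <- function(p) {
  stopifnot(is(p, "GradientField"))
  h <- p@horizontal; v <- p@vertical
  W <- ncol(h); H <- nrow(h)
  (h[, c(W, seq_len(W - 1)), drop = FALSE] - h) +
    (v[c(H, seq_len(H - 1)), , drop = FALSE] - v)
}

#' Total variation of an image
#'
#' Anisotropic (default): `sum(|Dh u| + |Dv u|)`; isotropic:
#' `sum(sqrt((Dh u)^2 + (Dv u)^2))`, both under periodic differences.
#'
#' @param u image matrix or single-channel [CSImage-class].
#' @param norm `"anisotropic"` (l1, the package default) or `"isotropic"` (l2).
#' @return a scalar.
#' @export
totalVariation <- function(u, norm = c("anisotropic", "isotropic")) {
  norm <- match.arg(norm)
  g <- imageGradient(u)
  if (norm == "anisotropic") sum(abs(g@horizontal)) + sum(abs(g@vertical))
  else sum(sqrt(g@horizontal^2 + g@vertical^2))
}

#' Soft thresholding (l1 shrinkage)
#'
#' `sgn(v) * max(|v| - t, 0)`, the exact minimizer of
#' `(z - v)^2 / 2 + t |z|` applied componentwise.
#'
#' @param v numeric array.
#' @param t threshold, >= 0.
#' @return shrunk array of the same shape.
#' @export
softThreshold <- function(v, t) {
  if (t < 0) stop("threshold must be >= 0")
  sign(v) * pmax(abs(v) - t, 0)
}

#' Closed-form gradient-split update
#'
#' Minimizes `tau ||w||_1 - <gamma, Du - w> + rhoTV/2 ||Du - w||^2` over the
#' split variable `w`, componentwise for each gradient direction
#' (anisotropic model): `w = softThreshold(Du - gamma / rhoTV, tau / rhoTV)`.
#'
#' @param Du gradient of the current image iterate ([GradientField-class]).
#' @param gamma Lagrange multiplier field ([GradientField-class]).
#' @param rhoTV penalty parameter, > 0.
#' @param tau TV weight, >= 0.
#' @return a [GradientField-class].
#' @export
solveWSubproblem <- function(Du, gamma, rhoTV, tau) {
  if (rhoTV <= 0) stop("rhoTV must be > 0")
  if (tau < 0) stop("tau must be >= 0")
  gradientField(
    horizontal = softThreshold(Du@horizontal - gamma@horizontal / rhoTV,
                               tau / rhoTV),
    vertical   = softThreshold(Du@vertical - gamma@vertical / rhoTV,
                               tau / rhoTV))
}
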