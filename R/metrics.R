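# Image-quality metrics: MSE, PSNR, SSIM.

#' Mean squared error between two images
#'
#' Mean of squared pixel differences; colour images average over all
#' channels.
#'
#' @param u,uHat [CSImage-class] objects or matrices of identical shape.
#' @return a scalar.
#' @export
imageMSE <- function(u, uHat) {
  a <- if (is(u, "CSImage")) pixels(u) else u
  b <- if (is(uHat, "CSImage")) pixels(uHat) else uHat
  if (!identical(dim(a), dim(b))) stop("images must share a shape")
  mean((a - b)^2)
}

#' Peak signal-to-noise ratio
#'
#' `10 log10((2^k - 1)^2 / MSE)` in dB for bit depth `k`. Identical images
#' give `Inf` with attribute `zeroMSE = TRUE` as an explicit sentinel.
#'
#' @param u,uHat images of identical shape.
#' @param k bit depth; defaults to the bit depth of `u` when it is a
#'   [CSImage-class], else 8.
#' @return PSNR in dB.
#' @examples
#' imagePSNR(matrix(0, 4, 4), matrix(255, 4, 4))   # 0 dB
#' @export
imagePSNR <- function(u, uHat, k = NULL) {
  if (is.null(k)) k <- if (is(u, "CSImage")) bitDepth(u) else 8L
  m <- imageMSE(u, uHat)
  if (m == 0) {
    out <- Inf
    attr(out, "zeroMSE") <- TRUE
    return(out)
  }
  10 * log10((2^k - 1)^2 / m)
}

#' SSIM configuration
#'
#' @slot K1,K2 the small stabilizing constants (`c1 = (K1 D)^2`,
#'   `c2 = (K2 D)^2`, `c3 = c2 / 2`).
#' @slot window `"sliding"` (mean of per-window values, the reporting
#'   default) or `"global"` (one value from whole-image moments).
#' @slot windowSize side of the uniform sliding window.
#' @slot clamp clamp the result into `[0, 1]`? Off by default: with
#'   `c3 = c2/2` anti-correlated images yield a negative structure term and
#'   the raw product is reported unless asked otherwise.
#' @seealso [ssimConfig()], [imageSSIM()]
#' @export
setClass("SSIMConfig",
  representation(K1 = "numeric", K2 = "numeric", window = "character",
                 windowSize = "integer", clamp = "logical"),
  validity = function(object) {
    if (object@K1 <= 0 || object@K2 <= 0) return("K1 and K2 must be > 0")
    if (!object@window %in% c("sliding", "global"))
      return("window must be 'sliding' or 'global'")
    if (object@windowSize < 2L) return("windowSize must be >= 2")
    TRUE
  }
)

#' @rdname SSIMConfig-class
#' @param K1,K2,window,windowSize,clamp see slots.
#' @return an `SSIMConfig`.
#' @export
ssimConfig <- function(K1 = 0.01, K2 = 0.03,
                       window = c("sliding", "global"), windowSize = 8L,
                       clamp = FALSE) {
  window <- match.arg(window)
  new("SSIMConfig", K1 = K1, K2 = K2, window = window,
      windowSize = as.integer(windowSize), clamp = clamp)
}

# Sliding-window local sums via separable running sums (valid positions).
boxSums <- function(m, w) {
  cs <- apply(m, 2, cumsum)
  cs <- rbind(0, cs)
  colPart <- cs[(w + 1):nrow(cs), , drop = FALSE] -
    cs[1:(nrow(cs) - w), , drop = FALSE]
  cs2 <- t(apply(colPart, 1, cumsum))
  if (nrow(colPart) == 1L) cs2 <- matrix(cs2, nrow = 1L)
  cs2 <- cbind(0, cs2)
  cs2[, (w + 1):ncol(cs2), drop = FALSE] -
    cs2[, 1:(ncol(cs2) - w), drop = FALSE]
}

ssimChannel <- function(a, b, config, D) {
  c1 <- (config@K1 * D)^2
  c2 <- (config@K2 * D)^2
  c3 <- c2 / 2
  lcs <- function(mua, mub, va, vb, vab) {
    sa <- sqrt(pmax(va, 0)); sb <- sqrt(pmax(vb, 0))
    l <- (2 * mua * mub + c1) / (mua^2 + mub^2 + c1)
    co <- (2 * sa * sb + c2) / (va + vb + c2)
    s <- (vab + c3) / (sa * sb + c3)
    l * co * s
  }
  if (config@window == "global") {
    n <- length(a)
    mua <- mean(a); mub <- mean(b)
    va <- stats::var(as.vector(a)); vb <- stats::var(as.vector(b))
    vab <- stats::cov(as.vector(a), as.vector(b))
    val <- lcs(mua, mub, va, vb, vab)
  } else {
    w <- config@windowSize
    if (nrow(a) < w || ncol(a) < w)
      stop("image smaller than the SSIM window")
    nw <- w * w
    sA <- boxSums(a, w); sB <- boxSums(b, w)
    sAA <- boxSums(a * a, w); sBB <- boxSums(b * b, w)
    sAB <- boxSums(a * b, w)
    mua <- sA / nw; mub <- sB / nw
    # unbiased (sample) variance/covariance per window
    va <- (sAA - sA^2 / nw) / (nw - 1)
    vb <- (sBB - sB^2 / nw) / (nw - 1)
    vab <- (sAB - sA * sB / nw) / (nw - 1)
    val <- mean(lcs(mua, mub, va, vb, vab))
  }
  val
}

#' Structural similarity index
#'
#' The product of luminance, contrast and structure comparisons,
#' `l = (2 mu_u mu_v + c1) / (mu_u^2 + mu_v^2 + c1)`,
#' `c = (2 s_u s_v + c2) / (s_u^2 + s_v^2 + c2)`,
#' `s = (s_uv + c3) / (s_u s_v + c3)`, with `c_i = (K_i D)^2`, `c3 = c2/2`,
#' and `D = 2^k - 1` the dynamic range. Sliding mode (default) averages the
#' per-window products over all fully-interior uniform windows; global mode
#' computes one product from whole-image moments. Identical images score
#' exactly 1; colour images average the per-channel scores.
#'
#' @param u,uHat images of identical shape.
#' @param config an [SSIMConfig-class].
#' @param k bit depth defining the dynamic range (default from `u` or 8).
#' @return a scalar (in `[-1, 1]`; `[0, 1]` when clamped).
#' @export
imageSSIM <- function(u, uHat, config = ssimConfig(), k = NULL) {
  if (is.null(k)) k <- if (is(u, "CSImage")) bitDepth(u) else 8L
  a <- if (is(u, "CSImage")) pixels(u) else u
  b <- if (is(uHat, "CSImage")) pixels(uHat) else uHat
  if (!identical(dim(a), dim(b))) stop("images must share a shape")
  D <- 2^k - 1
  val <- if (length(dim(a)) == 3L)
    mean(vapply(seq_len(dim(a)[3]), function(ch)
      ssimChannel(a[, , ch], b[, , ch], config, D), numeric(1)))
  else ssimChannel(a, b, config, D)
  if (config@clamp) val <- min(max(val, 0), 1)
  val
}
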