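# Wavelet-shrinkage denoising baseline: periodized orthogonal 2D DWT,
# soft/hard thresholding of all detail subbands with a single global
# threshold (universal threshold by default), inverse DWT. The periodized
# filter bank is exactly orthogonal at every dyadic level, so the transform
# conserves energy and shrinkage can only reduce it.

# Orthogonal analysis filters. db4 = Daubechies family, 4 vanishing
# moments (8 taps); the taps are the standard published constants.
waveletFilters <- function(name) {
  lo <- switch(name,
    haar = c(1, 1) / sqrt(2),
    db4 = c(0.23037781330885523, 0.71484657055254153, 0.63088076792959036,
            -0.02798376941698385, -0.18703481171888114, 0.03084138183598697,
            0.03288301166698295, -0.01059740178499728),
    stop("unknown wavelet: ", name, " (available: haar, db4)"))
  F <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(F) - 1)
  list(lo = lo, hi = hi)
}

# One periodic analysis step along the columns of x (length n even):
# a[k] = sum_j lo[j] x[(2k + j) mod n], likewise d with hi. Returns rbind(a, d).
dwtStepCols <- function(x, flt) {
  n <- nrow(x)
  F <- length(flt$lo)
  half <- n %/% 2L
  a <- matrix(0, half, ncol(x)); d <- matrix(0, half, ncol(x))
  for (j in seq_len(F)) {
    idx <- ((2L * (seq_len(half) - 1L) + j - 1L) %% n) + 1L
    a <- a + flt$lo[j] * x[idx, , drop = FALSE]
    d <- d + flt$hi[j] * x[idx, , drop = FALSE]
  }
  list(a = a, d = d)
}

# Adjoint (= inverse, orthogonal bank) of dwtStepCols.
idwtStepCols <- function(a, d, flt) {
  half <- nrow(a)
  n <- 2L * half
  F <- length(flt$lo)
  x <- matrix(0, n, ncol(a))
  for (j in seq_len(F)) {
    idx <- ((2L * (seq_len(half) - 1L) + j - 1L) %% n) + 1L
    for (col in seq_len(ncol(a))) {
      x[idx, col] <- x[idx, col] + flt$lo[j] * a[, col] + flt$hi[j] * d[, col]
    }
  }
  x
}

# Multilevel 2D periodized DWT. Returns list(approx, details) where details
# is a list (coarsest first) of list(lh, hl, hh).
dwt2Periodic <- function(x, wavelet = "db4", levels = 1L) {
  flt <- waveletFilters(wavelet)
  details <- vector("list", levels)
  cur <- x
  for (lev in seq_len(levels)) {
    if (nrow(cur) %% 2L != 0L || ncol(cur) %% 2L != 0L)
      stop("image size does not support ", levels, " decomposition levels")
    sc <- dwtStepCols(cur, flt)               # split rows (along columns)
    sl <- dwtStepCols(t(sc$a), flt)           # split columns of approx rows
    sh <- dwtStepCols(t(sc$d), flt)
    cur <- t(sl$a)
    details[[lev]] <- list(lh = t(sl$d), hl = t(sh$a), hh = t(sh$d))
  }
  list(approx = cur, details = rev(details), wavelet = wavelet,
       levels = levels)
}

idwt2Periodic <- function(dec) {
  flt <- waveletFilters(dec$wavelet)
  cur <- dec$approx
  for (det in dec$details) {
    low <- t(idwtStepCols(t(cur), t(det$lh), flt))
    # note: idwtStepCols expects matrices oriented as its forward partner
    high <- t(idwtStepCols(t(det$hl), t(det$hh), flt))
    cur <- idwtStepCols(low, high, flt)
  }
  cur
}

#' Universal threshold
#'
#' The classical wavelet-denoising threshold `sigma * sqrt(2 ln N)` for a
#' noise standard deviation `sigma` and pixel count `N` (natural log).
#'
#' @param sigma noise standard deviation, >= 0.
#' @param nPixels number of pixels, >= 1.
#' @return the threshold (intensity units).
#' @examples
#' universalThreshold(20, 256^2)
#' @export
universalThreshold <- function(sigma, nPixels) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (nPixels < 1) stop("nPixels must be >= 1")
  sigma * sqrt(2 * log(nPixels))
}

#' Robust noise-level estimate (wavelet MAD)
#'
#' `median(|finest diagonal detail coefficients|) / 0.6745`, the standard
#' robust estimator of an additive Gaussian noise level; insensitive to
#' adding a constant to the image.
#'
#' @param image single-channel [CSImage-class] or matrix (colour images:
#'   the channel estimates are averaged).
#' @param wavelet `"db4"` (default) or `"haar"`.
#' @return estimated standard deviation in intensity units.
#' @export
estimateSigmaMAD <- function(image, wavelet = "db4") {
  if (is(image, "CSImage") && nChannels(image) == 3L) {
    px <- pixels(image)
    return(mean(vapply(1:3, function(ch)
      estimateSigmaMAD(px[, , ch], wavelet), numeric(1))))
  }
  px <- asPixelMatrix(image)
  hh <- dwt2Periodic(px, wavelet, 1L)$details[[1]]$hh
  stats::median(abs(hh)) / 0.6745
}

#' Wavelet denoising configuration
#'
#' @slot wavelet orthogonal wavelet name (`"db4"` or `"haar"`).
#' @slot levels decomposition depth `J >= 1`.
#' @slot mode `"soft"` (shrinkage) or `"hard"` (keep-or-kill).
#' @slot threshold numeric threshold `S` in intensity units, or `NA` for the
#'   universal threshold `sigma * sqrt(2 ln N)`.
#' @slot sigma noise level for the universal threshold; `NA` = MAD estimate.
#' @seealso [waveletConfig()], [waveletDenoise()]
#' @export
setClass("WaveletConfig",
  representation(wavelet = "character", levels = "integer",
                 mode = "character", threshold = "numeric", sigma = "numeric"),
  validity = function(object) {
    if (object@levels < 1L) return("levels must be >= 1")
    if (!object@mode %in% c("soft", "hard"))
      return("mode must be 'soft' or 'hard'")
    if (!is.na(object@threshold) && object@threshold < 0)
      return("threshold must be >= 0")
    TRUE
  }
)

#' @rdname WaveletConfig-class
#' @param wavelet,levels,mode,threshold,sigma see slots.
#' @return a `WaveletConfig`.
#' @export
waveletConfig <- function(wavelet = "db4", levels = 4L,
                          mode = c("soft", "hard"), threshold = NA_real_,
                          sigma = NA_real_) {
  mode <- match.arg(mode)
  new("WaveletConfig", wavelet = wavelet, levels = as.integer(levels),
      mode = mode, threshold = threshold, sigma = sigma)
}

setMethod("show", "WaveletConfig", function(object) {
  cat(sprintf("WaveletConfig: %s, J=%d, %s threshold=%s sigma=%s\n",
              object@wavelet, object@levels, object@mode,
              format(object@threshold), format(object@sigma)))
})

#' Wavelet-shrinkage denoising
#'
#' Multilevel orthogonal DWT, thresholding of every detail subband at every
#' level with a single global threshold (the approximation subband is left
#' untouched), inverse DWT. Soft thresholding maps a coefficient `d` to
#' `sgn(d) max(|d| - S, 0)`; hard thresholding keeps `d` unchanged when
#' `|d| > S` and zeroes it otherwise. The default threshold is the universal
#' threshold with a MAD-estimated noise level.
#'
#' @param image a [CSImage-class] (colour images processed per channel).
#' @param config a [WaveletConfig-class].
#' @return the denoised [CSImage-class].
#' @examples
#' ph <- makePhantom(64, 64, seed = 1)
#' noisy <- addGaussianNoise(ph, 20, seed = 2)
#' den <- waveletDenoise(noisy, waveletConfig(sigma = 20))
#' @export
waveletDenoise <- function(image, config = waveletConfig()) {
  stopifnot(is(image, "CSImage"))
  mapChannels(image, function(px) {
    S <- config@threshold
    if (is.na(S)) {
      sigma <- config@sigma
      if (is.na(sigma)) sigma <- estimateSigmaMAD(px, config@wavelet)
      S <- universalThreshold(sigma, length(px))
    }
    dec <- dwt2Periodic(px, config@wavelet, config@levels)
    shrink <- if (config@mode == "soft")
      function(d) sign(d) * pmax(abs(d) - S, 0)
    else
      function(d) d * (abs(d) > S)
    dec$details <- lapply(dec$details, function(det) lapply(det, shrink))
    idwt2Periodic(dec)
  })
}
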