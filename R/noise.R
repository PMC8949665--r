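# Noise simulators. Both draw from a single seeded stream in row-major pixel
# order (channel by channel for colour images) so results are reproducible;
# the generator algorithm is RNGkind()[1] and is recorded in run logs.

#' Add white Gaussian noise
#'
#' Adds independent `Gaussian(mean, sigma^2)` noise to every pixel. The
#' result is unclipped by default: the solver operates on unconstrained
#' reals and clipping to the representable range happens only at export
#' (set `clip = TRUE` to clip here instead, and record having done so).
#'
#' @param image a [CSImage-class].
#' @param sigma noise standard deviation, intensity units, >= 0.
#' @param mean noise mean, intensity units.
#' @param seed integer seed.
#' @param clip clip the noisy image to `[0, 2^k - 1]`? Default `FALSE`.
#' @return a [CSImage-class].
#' @export
addGaussianNoise <- function(image, sigma, mean = 0, seed = 0L, clip = FALSE) {
  stopifnot(is(image, "CSImage"))
  if (sigma < 0) stop("sigma must be >= 0")
  d <- dim(pixels(image))
  withSeed(seed, {
    out <- mapChannels(image, function(ch)
      ch + matRowMajor(stats::rnorm(d[1] * d[2], mean, sigma), d[1], d[2]))
    if (clip) out <- csImage(pmin(pmax(pixels(out), 0), dynamicRange(out)),
                             bitDepth(out))
    out
  })
}

#' Add salt-and-pepper noise
#'
#' Each pixel is independently replaced by the salt intensity `vMax` with
#' probability `q1`, by the pepper intensity `vMin` with probability `q2`,
#' and left bit-identical otherwise. The total level is `q = q1 + q2`; when
#' only `q` is given it is split evenly between salt and pepper.
#'
#' @param image a [CSImage-class].
#' @param q total noise level; used only when `q1`/`q2` are not given.
#' @param q1,q2 salt and pepper probabilities, `q1 + q2 <= 1`.
#' @param vMax salt intensity; `NA` (default) means `2^k - 1`.
#' @param vMin pepper intensity; default 0.
#' @param seed integer seed.
#' @return a [CSImage-class].
#' @export
addSaltPepperNoise <- function(image, q = NULL, q1 = NULL, q2 = NULL,
                               vMax = NA_real_, vMin = 0, seed = 0L) {
  stopifnot(is(image, "CSImage"))
  if (is.null(q1) && is.null(q2)) {
    if (is.null(q)) stop("give either q or q1/q2")
    q1 <- q / 2; q2 <- q / 2
  }
  q1 <- q1 %||% 0; q2 <- q2 %||% 0
  if (q1 < 0 || q2 < 0) stop("q1 and q2 must be >= 0")
  if (q1 + q2 > 1) stop("q1 + q2 must be <= 1")
  if (is.na(vMax)) vMax <- dynamicRange(image)
  d <- dim(pixels(image))
  withSeed(seed, {
    mapChannels(image, function(ch) {
      u <- matRowMajor(stats::runif(d[1] * d[2]), d[1], d[2])
      ch[u < q1] <- vMax
      ch[u >= q1 & u < q1 + q2] <- vMin
      ch
    })
  })
}

#' Apply a NoiseSpec to an image
#'
#' Dispatches to [addGaussianNoise()] or [addSaltPepperNoise()] according to
#' the spec's kind.
#'
#' @param image a [CSImage-class].
#' @param spec a [NoiseSpec-class].
#' @param seed integer seed.
#' @param clip clip AWGN output to the representable range? Default `FALSE`.
#' @return a [CSImage-class].
#' @export
applyNoise <- function(image, spec, seed = 0L, clip = FALSE) {
  stopifnot(is(spec, "NoiseSpec"))
  if (spec@kind == "awgn")
    addGaussianNoise(image, spec@sigma, spec@mean, seed = seed, clip = clip)
  else
    addSaltPepperNoise(image, q1 = spec@q1, q2 = spec@q2,
                       vMax = spec@vMax, vMin = spec@vMin, seed = seed)
}
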