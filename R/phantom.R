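#' Synthetic phantom with piecewise-constant shapes and periodic texture
#'
#' Generates a deterministic test image that exercises both regularizers of
#' the reconstruction model: overlapping constant-intensity rectangles and
#' disks (favouring total variation) on a flat background, plus a strip tiled
#' with an exactly periodic random texture of period `texturePeriod`
#' (favouring the nonlocal self-similarity model: every block inside the
#' strip has many exact duplicates within a modest search window). It stands
#' in for external photographic test material; intensities are integers in
#' `[0, 255]`.
#'
#' The texture strip spans the bottom of the image: its height is half the
#' image height rounded down to a whole number of periods and its width the
#' largest multiple of the period that fits. Set `texturePeriod = 0` to omit
#' the texture (with `nShapes = 0` this yields a constant image with zero
#' total variation).
#'
#' @param height,width image size in pixels, each >= 32.
#' @param texturePeriod texture period in pixels (>= 2), or 0 for no texture.
#' @param nShapes number of random shapes to draw.
#' @param seed integer seed; the same seed always yields the same image.
#' @return an 8-bit [CSImage-class].
#' @examples
#' ph <- makePhantom(64, 64, texturePeriod = 8, nShapes = 3, seed = 1)
#' range(pixels(ph))
#' @export
makePhantom <- function(height = 256L, width = 256L, texturePeriod = 8L,
                        nShapes = 6L, seed = 0L) {
  if (height < 32L || width < 32L) stop("phantom must be at least 32 x 32")
  if (texturePeriod != 0L && texturePeriod < 2L)
    stop("texturePeriod must be 0 (none) or >= 2")
  withSeed(seed, {
    px <- matrix(120, height, width)
    for (s in seq_len(nShapes)) {
      val <- sample(16:240, 1)
      if (s %% 2L == 1L) {   # rectangle
        h <- sample(seq(height %/% 8, height %/% 2), 1)
        w <- sample(seq(width %/% 8, width %/% 2), 1)
        r0 <- sample(seq_len(height - h), 1)
        c0 <- sample(seq_len(width - w), 1)
        px[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- val
      } else {               # disk
        rad <- sample(seq(height %/% 12, height %/% 5), 1)
        cr <- sample(seq_len(height), 1)
        cc <- sample(seq_len(width), 1)
        rows <- matrix(seq_len(height), height, width)
        cols <- matrix(seq_len(width), height, width, byrow = TRUE)
        px[(rows - cr)^2 + (cols - cc)^2 <= rad^2] <- val
      }
    }
    if (texturePeriod > 0L) {
      p <- as.integer(texturePeriod)
      rh <- max(p, ((height %/% 2L) %/% p) * p)
      rh <- min(rh, (height %/% p) * p)
      cw <- (width %/% p) * p
      # random tile, cyclically smoothed so the texture's spectrum decays
      # like natural texture instead of being white (a raw uniform tile
      # would make the strip noise-like and defeat every smoothing prior)
      tile <- matrix(stats::runif(p * p), p, p)
      if (p >= 3L) {
        sm <- matrix(0, p, p)
        for (di in -1:1) for (dj in -1:1) {
          ri <- (seq_len(p) - 1L + di) %% p + 1L
          ci <- (seq_len(p) - 1L + dj) %% p + 1L
          sm <- sm + tile[ri, ci]
        }
        tile <- sm / 9
      }
      tile <- round((tile - min(tile)) / max(diff(range(tile)), 1e-12) * 70 + 85)
      strip <- tile[(seq_len(rh) - 1L) %% p + 1L, (seq_len(cw) - 1L) %% p + 1L]
      px[(height - rh + 1L):height, seq_len(cw)] <- strip
    }
    csImage(px, 8L)
  })
}
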