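# Orthonormal DCT-II and its inverse. The fast paths compute the length-n
# transform through a length-4n FFT (real result up to roundoff), giving
# O(n log n) sensing-operator applications; small dense matrices back the
# block transforms and the test oracles.

#' Orthonormal DCT-II matrix
#'
#' Returns the n x n orthonormal DCT-II matrix `C` with
#' `C[k+1, j+1] = s_k cos(pi k (2j + 1) / (2n))`, `s_0 = sqrt(1/n)`,
#' `s_k = sqrt(2/n)` otherwise, so `C %*% t(C)` is the identity.
#'
#' @param n transform length, >= 1.
#' @return an n x n matrix.
#' @export
dctMatrix <- function(n) {
  j <- 0:(n - 1)
  C <- outer(j, j, function(k, j) cos(pi * k * (2 * j + 1) / (2 * n)))
  C * c(sqrt(1 / n), rep(sqrt(2 / n), n - 1))
}

# Forward orthonormal DCT-II of a vector, via a length-4n FFT:
# embedding x at the odd positions of a symmetric length-4n sequence makes
# the FFT real with entries 2 * sum_j x_j cos(pi k (2j+1) / (2n)).
dctOrtho <- function(x) {
  n <- length(x)
  if (n == 1L) return(x)
  z <- numeric(4L * n)
  z[2L * seq_len(n)] <- x                 # positions 2j+1 (0-based), j=0..n-1
  z[4L * n - 2L * seq_len(n) + 2L] <- x   # mirrored positions 4n-1-2j
  c0 <- Re(stats::fft(z))[seq_len(n)] / 2
  c0 * c(sqrt(1 / n), rep(sqrt(2 / n), n - 1))
}

# Inverse (= transpose) of the orthonormal DCT-II, same FFT embedding run
# backwards: build the conjugate-symmetric length-4n spectrum and read the
# odd samples of its inverse FFT.
idctOrtho <- function(y) {
  n <- length(y)
  if (n == 1L) return(y)
  d <- y * c(sqrt(1 / n), rep(sqrt(2 / n), n - 1))
  D <- numeric(4L * n)
  D[1L] <- 2 * d[1L]
  if (n > 1L) {
    D[2:n] <- d[2:n]
    D[(4L * n):(3L * n + 2L)] <- d[2:n]
  }
  v <- Re(stats::fft(D, inverse = TRUE)) / (4 * n)
  2 * n * v[2L * seq_len(n)]
}
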