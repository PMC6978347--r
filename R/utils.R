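#' @useDynLib helixlattice, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef fft lm mad median nls optimize quantile rnorm runif
#'   sd setNames var vcov predict rlnorm
#' @importFrom utils head read.csv write.csv tail
NULL

# run code under a fixed RNG seed without disturbing the caller's stream
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# index of the origin (DC) pixel after fftshift, 1-based
fft_center <- function(n) as.integer(n %/% 2 + 1)

# circularly shift a matrix/array so the DC component sits at fft_center
fftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  sr <- fft_center(nr) - 1L; sc <- fft_center(nc) - 1L
  m[c(seq.int(nr - sr + 1L, nr), seq_len(nr - sr)),
    c(seq.int(nc - sc + 1L, nc), seq_len(nc - sc))]
}

# signed frequency (cycles per sample) of each index after fftshift
freq_axis <- function(n) (seq_len(n) - fft_center(n)) / n

# bilinear sampling of matrix values at fractional (row, col) positions;
# out-of-bounds samples return `fill`
bilinear_sample <- function(m, ri, ci, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(ri); c0 <- floor(ci)
  fr <- ri - r0; fc <- ci - c0
  ok <- r0 >= 1 & r0 <= nr - 1 & c0 >= 1 & c0 <= nc - 1
  out <- rep(fill, length(ri))
  if (any(ok)) {
    r0k <- r0[ok]; c0k <- c0[ok]; frk <- fr[ok]; fck <- fc[ok]
    i00 <- cbind(r0k, c0k); i10 <- cbind(r0k + 1, c0k)
    i01 <- cbind(r0k, c0k + 1); i11 <- cbind(r0k + 1, c0k + 1)
    out[ok] <- m[i00] * (1 - frk) * (1 - fck) + m[i10] * frk * (1 - fck) +
      m[i01] * (1 - frk) * fck + m[i11] * frk * fck
  }
  out
}

# separable periodic Gaussian smoothing of a 3D array (sigma in voxels),
# via FFT; content is assumed to sit away from the wrap-around edges
gauss_smooth3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  kern1 <- function(n) {
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) # unshifted distance to origin
    k <- exp(-x^2 / (2 * sigma^2))
    k / sum(k)
  }
  K <- outer(outer(kern1(d[1]), kern1(d[2])), kern1(d[3]))
  Re(fft(fft(a) * fft(K), inverse = TRUE)) / prod(d)
}
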