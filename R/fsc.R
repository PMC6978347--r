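#' Fourier shell correlation between two volumes
#'
#' Normalized complex correlation per reciprocal-space shell:
#' FSC(s) = Re(sum F_a conj(F_b)) / sqrt(sum|F_a|^2 sum|F_b|^2), evaluated
#' over spherical shells of Fourier pixels.
#'
#' @param vol_a,vol_b \code{volume_grid}s (or bare 3D arrays) of identical
#'   shape and voxel size.
#' @param voxel_A voxel size in Angstrom; taken from the grids when omitted.
#' @param shell_width shell thickness in Fourier pixels (default 1).
#' @return An \code{fsc_curve}: data frame with \code{shell} (index),
#'   \code{freq} (shell center, 1/Angstrom) and \code{fsc}.
#' @export
fsc <- function(vol_a, vol_b, voxel_A = NULL, shell_width = 1) {
  va <- if (inherits(vol_a, "volume_grid")) vol_a$values else vol_a
  vb <- if (inherits(vol_b, "volume_grid")) vol_b$values else vol_b
  if (!identical(dim(va), dim(vb))) stop("volumes must have identical shape")
  if (is.null(voxel_A)) {
    voxel_A <- if (inherits(vol_a, "volume_grid")) vol_a$voxel else 1
    if (inherits(vol_a, "volume_grid") && inherits(vol_b, "volume_grid") &&
        !isTRUE(all.equal(vol_a$voxel, vol_b$voxel))) {
      stop("volumes must share a voxel size")
    }
  }
  d <- dim(va)
  Fa <- fft(va); Fb <- fft(vb)
  fx <- freq_axis_unshifted(d[1])
  fy <- freq_axis_unshifted(d[2])
  fz <- freq_axis_unshifted(d[3])
  # radius in Fourier pixels of the smallest dimension's scale
  r <- sqrt(outer(outer(fx^2, fy^2, "+"), fz^2, "+")) * min(d)
  shell <- floor(r / shell_width)
  nmax <- floor(0.5 * min(d) / shell_width)
  keep <- shell <= nmax
  shell_f <- factor(shell[keep], levels = 0:nmax)
  num <- tapply(Re(Fa[keep] * Conj(Fb[keep])), shell_f, sum)
  da <- tapply(Mod(Fa[keep])^2, shell_f, sum)
  db <- tapply(Mod(Fb[keep])^2, shell_f, sum)
  val <- as.numeric(num) / sqrt(as.numeric(da) * as.numeric(db))
  freq <- (as.numeric(levels(shell_f)) + 0.5) * shell_width /
    (min(d) * voxel_A)
  freq[1] <- 0
  out <- data.frame(shell = as.integer(levels(shell_f)), freq = freq,
                    fsc = val)
  out <- out[is.finite(out$fsc) | out$shell == 0, , drop = FALSE]
  class(out) <- c("fsc_curve", "data.frame")
  out
}

freq_axis_unshifted <- function(n) {
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  k / n
}

#' Resolution at an FSC threshold
#'
#' The reciprocal of the frequency where the curve first crosses below the
#' threshold, linearly interpolated between shells. The conventional
#' thresholds are 0.143 (map vs map half-set criterion) and 0.5.
#'
#' @param curve an \code{fsc_curve} from \code{\link{fsc}}.
#' @param threshold FSC threshold (default 0.143).
#' @return Resolution in Angstrom (Inf if the curve never rises above the
#'   threshold at low frequency; NA if it never crosses below).
#' @export
resolution_at <- function(curve, threshold = 0.143) {
  f <- curve$freq
  y <- curve$fsc
  if (y[1] < threshold) return(Inf)
  below <- which(y < threshold)
  if (!length(below)) return(NA_real_)
  i <- below[1]
  # linear interpolation between shells i-1 and i
  f_cross <- f[i - 1] + (threshold - y[i - 1]) * (f[i] - f[i - 1]) /
    (y[i] - y[i - 1])
  1 / f_cross
}

#' @export
print.fsc_curve <- function(x, ...) {
  cat(sprintf("fsc_curve: %d shells to %.4g 1/A; resolution %.3g A (0.143), %.3g A (0.5)\n",
              nrow(x), max(x$freq),
              resolution_at(x, 0.143), resolution_at(x, 0.5)))
  invisible(x)
}

#' @export
plot.fsc_curve <- function(x, ...) {
  graphics::plot(x$freq, x$fsc, type = "l", xlab = "spatial frequency (1/A)",
                 ylab = "FSC", ylim = c(min(0, min(x$fsc)), 1), ...)
  graphics::abline(h = c(0.143, 0.5), lty = 3)
  invisible(x)
}
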