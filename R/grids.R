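#' Calibrated 2D image grid
#'
#' Wraps a numeric matrix with its pixel size. First index = radial axis (R),
#' second index = axial/helix axis (Z); the grid center (\code{floor(n/2)+1})
#' is the helix axis / image origin.
#'
#' @param values numeric matrix.
#' @param pixel_A pixel size in Angstrom per pixel (> 0).
#' @return An \code{image_grid} object.
#' @export
image_grid <- function(values, pixel_A) {
  values <- as.matrix(values)
  if (!is.numeric(pixel_A) || pixel_A <= 0) stop("pixel_A must be > 0")
  if (any(!is.finite(values))) stop("image values must be finite")
  structure(list(values = values, pixel_A = pixel_A), class = "image_grid")
}

#' Calibrated 3D volume grid
#'
#' @param values numeric 3D array.
#' @param voxel voxel size (> 0), in the unit given by \code{unit}.
#' @param unit physical unit of \code{voxel}: "A" for Angstrom volumes
#'   (cryo-EM maps), "nm" for tomograms.
#' @return A \code{volume_grid} object.
#' @export
volume_grid <- function(values, voxel, unit = c("A", "nm")) {
  unit <- match.arg(unit)
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  if (!is.numeric(voxel) || voxel <= 0) stop("voxel size must be > 0")
  if (any(!is.finite(values))) stop("volume values must be finite")
  structure(list(values = values, voxel = voxel, unit = unit),
            class = "volume_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("image_grid: %d x %d pixels, %.4g A/px\n",
              nrow(x$values), ncol(x$values), x$pixel_A))
  invisible(x)
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("volume_grid: %d x %d x %d voxels, %.4g %s/voxel\n",
              d[1], d[2], d[3], x$voxel, x$unit))
  invisible(x)
}

#' Add white Gaussian noise at a given signal-to-noise ratio
#'
#' Noise variance = var(signal) / snr. Reproducible under a fixed seed; the
#' caller's RNG stream is left untouched.
#'
#' @param grid an \code{image_grid} or \code{volume_grid} (or bare array).
#' @param snr positive signal-to-noise ratio (variance ratio).
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @return Grid of the same class with noise added.
#' @export
add_noise <- function(grid, snr, seed = NULL) {
  if (!is.numeric(snr) || length(snr) != 1L || !is.finite(snr) && !is.infinite(snr) || snr <= 0) {
    stop("snr must be a positive number")
  }
  v <- if (inherits(grid, c("image_grid", "volume_grid"))) grid$values else grid
  if (is.infinite(snr)) return(grid)
  sv <- var(as.vector(v))
  if (sv <= 0) stop("signal variance must be > 0")
  noise <- local_seed(seed, rnorm(length(v), sd = sqrt(sv / snr)))
  vn <- v + array(noise, dim = dim(v) %||% length(v))
  if (inherits(grid, c("image_grid", "volume_grid"))) {
    grid$values <- vn
    grid
  } else {
    vn
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
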