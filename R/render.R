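#' Build a point model of a helical filament
#'
#' Places a motif (offsets about a nominal cylindrical radius) on every
#' subunit of a helical lattice via \code{\link{expand_symmetry}}. The total
#' point count is \code{n_subunits * nrow(motif) * axial_cyclic * (2 if
#' dihedral)}.
#'
#' @param sym a \code{helical_symmetry}.
#' @param radius_A nominal cylindrical radius of the motif origin, Angstrom.
#' @param motif numeric matrix of (x, y, z) offsets (Angstrom) applied after
#'   translating to \code{radius_A} along x; default a single point.
#' @param n_subunits number of screw steps generated (>= 2).
#' @param weights per-motif-point positive weights (recycled).
#' @return A \code{point_model}: data frame of points plus provenance.
#' @export
build_filament_model <- function(sym, radius_A, motif = matrix(0, 1, 3),
                                 n_subunits, weights = 1) {
  stopifnot(inherits(sym, "helical_symmetry"))
  n_subunits <- as.integer(n_subunits)
  if (is.na(n_subunits) || n_subunits < 2L) stop("n_subunits must be >= 2")
  motif <- as.matrix(motif)
  if (ncol(motif) != 3L) stop("motif must be an n x 3 matrix of offsets")
  weights <- rep_len(weights, nrow(motif))
  if (any(weights <= 0)) stop("weights must be positive")
  asu <- sweep(motif, 2, c(radius_A, 0, 0), "+")
  pts <- expand_symmetry(sym, asu, count = n_subunits,
                         start_index = -(n_subunits %/% 2))
  pts$weight <- rep(weights, times = nrow(pts) / nrow(motif))
  structure(list(points = pts, sym = sym, radius_A = radius_A),
            class = "point_model")
}

#' @export
print.point_model <- function(x, ...) {
  cat(sprintf("point_model: %d points at nominal radius %.3g A\n",
              nrow(x$points), x$radius_A))
  print(x$sym)
  invisible(x)
}

#' Render a point model as a 2D projection or 3D volume of Gaussian blobs
#'
#' Each point contributes an isotropic Gaussian blob of standard deviation
#' \code{blob_sigma_A}; 2D rendering projects along y (the filament axis z is
#' the second image axis). Density is in weight per Angstrom^2 (2D) or
#' Angstrom^3 (3D), so that \code{sum(values) * pixel^d} equals the total
#' weight when the grid contains the +-4 sigma support. Points whose support
#' falls outside the grid are clipped with a warning.
#'
#' @param model a \code{point_model}.
#' @param shape integer vector: \code{c(nx, nz)} for a projection or
#'   \code{c(nx, ny, nz)} for a volume.
#' @param pixel_A pixel/voxel size, Angstrom.
#' @param blob_sigma_A blob standard deviation, Angstrom (>= pixel_A).
#' @return An \code{image_grid} or \code{volume_grid} (unit "A").
#' @export
render_model <- function(model, shape, pixel_A, blob_sigma_A) {
  stopifnot(inherits(model, "point_model"))
  if (blob_sigma_A < pixel_A) stop("blob_sigma_A must be >= pixel size")
  d <- length(shape)
  if (!d %in% c(2L, 3L)) stop("shape must have length 2 (image) or 3 (volume)")
  pts <- model$points
  if (d == 2L) {
    vals <- render_gauss2(cbind(pts$x, pts$z), pts$weight, shape, pixel_A,
                          blob_sigma_A)
    image_grid(vals, pixel_A)
  } else {
    vals <- render_gauss3(cbind(pts$x, pts$y, pts$z), pts$weight, shape,
                          pixel_A, blob_sigma_A)
    volume_grid(vals, pixel_A, unit = "A")
  }
}

render_gauss2 <- function(xy, w, shape, px, sigma) {
  n1 <- shape[1]; n2 <- shape[2]
  out <- matrix(0, n1, n2)
  c1 <- fft_center(n1); c2 <- fft_center(n2)
  hw <- ceiling(4 * sigma / px)
  norm <- px^2 / (2 * pi * sigma^2)  # density units: weight per A^2
  clipped <- 0L
  for (k in seq_len(nrow(xy))) {
    i0 <- xy[k, 1] / px + c1
    j0 <- xy[k, 2] / px + c2
    ii <- seq.int(floor(i0) - hw, ceiling(i0) + hw)
    jj <- seq.int(floor(j0) - hw, ceiling(j0) + hw)
    iin <- ii[ii >= 1 & ii <= n1]; jjn <- jj[jj >= 1 & jj <= n2]
    if (length(iin) < length(ii) || length(jjn) < length(jj)) clipped <- clipped + 1L
    if (!length(iin) || !length(jjn)) next
    gi <- exp(-((iin - i0) * px)^2 / (2 * sigma^2))
    gj <- exp(-((jjn - j0) * px)^2 / (2 * sigma^2))
    out[iin, jjn] <- out[iin, jjn] + (w[k] * norm / px^2) * outer(gi, gj)
  }
  if (clipped > 0L) warning(sprintf("%d blob(s) clipped at the grid edge", clipped))
  out
}

render_gauss3 <- function(xyz, w, shape, px, sigma) {
  n <- shape
  out <- array(0, dim = n)
  ctr <- vapply(n, fft_center, integer(1))
  hw <- ceiling(4 * sigma / px)
  clipped <- 0L
  for (k in seq_len(nrow(xyz))) {
    p0 <- xyz[k, ] / px + ctr
    rng <- lapply(1:3, function(a) {
      v <- seq.int(floor(p0[a]) - hw, ceiling(p0[a]) + hw)
      v[v >= 1 & v <= n[a]]
    })
    if (any(vapply(rng, length, integer(1)) == 0L)) { clipped <- clipped + 1L; next }
    g <- lapply(1:3, function(a)
      exp(-((rng[[a]] - p0[a]) * px)^2 / (2 * sigma^2)))
    blob <- outer(outer(g[[1]], g[[2]]), g[[3]])
    amp <- w[k] / (2 * pi * sigma^2)^1.5
    out[rng[[1]], rng[[2]], rng[[3]]] <- out[rng[[1]], rng[[2]], rng[[3]]] +
      amp * blob
  }
  if (clipped > 0L) warning(sprintf("%d blob(s) clipped at the grid edge", clipped))
  out
}

#' Render a synthetic filament micrograph
#'
#' Convenience wrapper producing a tall projection image of one filament with
#' its axis vertical (optionally tilted in-plane), suitable for segment
#' excision and power-spectrum analysis.
#'
#' @param sym a \code{helical_symmetry}.
#' @param radius_A motif radius, Angstrom.
#' @param length_A filament length to cover, Angstrom.
#' @param pixel_A pixel size, Angstrom.
#' @param width_px image width in pixels.
#' @param blob_sigma_A blob sigma, Angstrom.
#' @param tilt_deg in-plane rotation of the filament axis away from vertical.
#' @param snr signal-to-noise variance ratio (Inf for noiseless).
#' @param seed RNG seed for the noise.
#' @return List with \code{image} (an \code{image_grid}) and \code{axis}, the
#'   filament axis polyline in Angstrom image coordinates (n x 2, columns
#'   x, z relative to image center).
#' @export
simulate_micrograph <- function(sym, radius_A, length_A, pixel_A,
                                width_px = 256L, blob_sigma_A = 2.5,
                                tilt_deg = 0, snr = Inf, seed = NULL) {
  n_sub <- as.integer(ceiling(length_A / sym$rise_A)) + 2L
  model <- build_filament_model(sym, radius_A, n_subunits = n_sub)
  if (tilt_deg != 0) {
    pts <- as.matrix(model$points[, c("x", "z")])
    th <- tilt_deg * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    rot <- pts %*% R
    model$points$x <- rot[, 1]
    model$points$z <- rot[, 2]
  }
  height_px <- as.integer(ceiling(length_A / pixel_A / 2) * 2)
  img <- suppressWarnings(
    render_model(model, c(width_px, height_px), pixel_A, blob_sigma_A))
  if (is.finite(snr)) img <- add_noise(img, snr, seed)
  half <- length_A / 2 - 1
  tt <- seq(-half, half, length.out = 33)
  th <- tilt_deg * pi / 180
  axis <- cbind(x = sin(th) * tt, z = cos(th) * tt)
  list(image = img, axis = axis)
}
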