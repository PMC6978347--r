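#' Specification of a synthetic filament tomogram
#'
#' Describes a field of short, gently curved tubes of the kind seen inside
#' phase-separated p62 bodies: tube diameter ~15 nm, lengths a few tens of
#' nm, loosely packed without contact.
#'
#' @param n_filaments number of tubes (>= 0).
#' @param diameter_mean_nm,diameter_sd_nm tube diameter distribution (nm).
#' @param length_meanlog,length_sdlog log-normal centerline-length
#'   parameters; the defaults give a mean length of 30 nm.
#' @param bend_sd_deg direction change per 2 nm step of the centerline walk
#'   (degrees; curvature scale).
#' @param voxel_nm voxel size (nm).
#' @param shape volume dimensions in voxels, c(nx, ny, nz).
#' @param snr signal-to-noise variance ratio of the rendered volume.
#' @param seed RNG seed.
#' @return A \code{tomogram_spec} list.
#' @export
tomogram_spec <- function(n_filaments = 20L,
                          diameter_mean_nm = 15, diameter_sd_nm = 1,
                          length_meanlog = log(30) - 0.3^2 / 2,
                          length_sdlog = 0.3,
                          bend_sd_deg = 4, voxel_nm = 1,
                          shape = c(160L, 160L, 80L), snr = 2,
                          seed = 1L) {
  if (diameter_mean_nm < 2 * voxel_nm) stop("diameter must be >= 2 voxels")
  structure(list(n_filaments = as.integer(n_filaments),
                 diameter_mean_nm = diameter_mean_nm,
                 diameter_sd_nm = diameter_sd_nm,
                 length_meanlog = length_meanlog,
                 length_sdlog = length_sdlog,
                 bend_sd_deg = bend_sd_deg, voxel_nm = voxel_nm,
                 shape = as.integer(shape), snr = snr,
                 seed = as.integer(seed)),
            class = "tomogram_spec")
}

#' Simulate a tomogram of curved tube-like filaments with ground truth
#'
#' Renders flat-capped solid tubes of unit density around smooth random
#' polylines (curvature-limited persistent walks), convolves with a 1-voxel
#' Gaussian to emulate limited resolution, and adds white Gaussian noise at
#' the requested SNR. Filaments are packed without contact; the exact
#' centerline and dimensions of every tube are returned as ground truth.
#' Pure function of the spec (including its seed).
#'
#' @param spec a \code{tomogram_spec}.
#' @param max_attempts placement attempts per filament before giving up.
#' @return List with \code{volume} (a \code{volume_grid}, unit nm),
#'   \code{ground_truth} (data frame: filament_id, length_nm, diameter_nm,
#'   n_nodes) and \code{centerlines} (list of n x 3 matrices, nm).
#' @export
simulate_tomogram <- function(spec, max_attempts = 2000L) {
  stopifnot(inherits(spec, "tomogram_spec"))
  local_seed(spec$seed, {
    d <- spec$shape
    ext <- d * spec$voxel_nm
    vol <- array(0, dim = d)
    gt <- list()
    lines <- list()
    placed_nodes <- matrix(numeric(0), 0, 3)
    placed_r <- numeric(0)

    if (spec$n_filaments > 0) for (fi in seq_len(spec$n_filaments)) {
      diam <- max(2 * spec$voxel_nm,
                  rnorm(1, spec$diameter_mean_nm, spec$diameter_sd_nm))
      len <- rlnorm(1, spec$length_meanlog, spec$length_sdlog)
      r <- diam / 2
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        path <- random_tube_path(len, spec$bend_sd_deg, ext, margin = r + 1)
        if (is.null(path)) next
        if (nrow(placed_nodes) > 0) {
          dmin <- min(cross_min_dist(path, placed_nodes))
          # keep a clear surface-to-surface gap so neighboring tubes stay
          # resolvable at the rendered resolution
          if (dmin < r + max(placed_r) + 4) next
        }
        ok <- TRUE
        break
      }
      if (!ok) {
        stop(sprintf(paste0("simulate_tomogram: could not place filament %d ",
                            "without contact after %d attempts ",
                            "(volume too small or too crowded)"),
                     fi, max_attempts))
      }
      vol <- add_tube(vol, path, r, spec$voxel_nm)
      seglen <- sqrt(rowSums(diff(path)^2))
      gt[[fi]] <- data.frame(filament_id = fi, length_nm = sum(seglen),
                             diameter_nm = diam, n_nodes = nrow(path))
      lines[[fi]] <- path
      placed_nodes <- rbind(placed_nodes, path)
      placed_r <- c(placed_r, r)
    }

    vol <- gauss_smooth3(vol, sigma = 1)  # 1-voxel Gaussian, resolution proxy
    if (is.finite(spec$snr) && spec$n_filaments > 0) {
      vol <- add_noise(vol, spec$snr, seed = NULL)
    }
    truth <- if (length(gt)) do.call(rbind, gt) else
      data.frame(filament_id = integer(0), length_nm = numeric(0),
                 diameter_nm = numeric(0), n_nodes = integer(0))
    list(volume = volume_grid(vol, spec$voxel_nm, unit = "nm"),
         ground_truth = truth, centerlines = lines)
  })
}

# persistent random walk of total arc length `len` inside the box, nm
random_tube_path <- function(len, bend_sd_deg, ext, margin, step = 2) {
  n_steps <- max(2L, ceiling(len / step))
  step_len <- len / n_steps
  start <- runif(3, margin, ext - margin)
  # random initial direction
  v <- rnorm(3); v <- v / sqrt(sum(v^2))
  path <- matrix(NA_real_, n_steps + 1, 3)
  path[1, ] <- start
  for (i in seq_len(n_steps)) {
    # perturb direction by a small random rotation
    perp <- rnorm(3); perp <- perp - sum(perp * v) * v
    pn <- sqrt(sum(perp^2))
    if (pn > 0) {
      ang <- rnorm(1, 0, bend_sd_deg) * pi / 180
      v <- cos(ang) * v + sin(ang) * perp / pn
      v <- v / sqrt(sum(v^2))
    }
    nxt <- path[i, ] + step_len * v
    if (any(nxt < margin) || any(nxt > ext - margin)) return(NULL)
    path[i + 1, ] <- nxt
  }
  path
}

# min distance from each row of a to the node set b (coarse contact check)
cross_min_dist <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    sqrt(min((b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2 +
               (b[, 3] - a[i, 3])^2))
  }, numeric(1))
}

# rasterize a flat-capped tube of radius r (nm) around a polyline into vol
add_tube <- function(vol, path, r, voxel) {
  d <- dim(vol)
  nseg <- nrow(path) - 1L
  lo <- pmax(floor((apply(path, 2, min) - r) / voxel), 1)
  hi <- pmin(ceiling((apply(path, 2, max) + r) / voxel), d)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  # voxel centers, nm
  gx <- (ix - 0.5) * voxel; gy <- (iy - 0.5) * voxel; gz <- (iz - 0.5) * voxel
  G <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  inside <- rep(FALSE, nrow(G))
  for (s in seq_len(nseg)) {
    a <- path[s, ]; b <- path[s + 1, ]
    ab <- b - a
    L2 <- sum(ab^2)
    t <- ((G[, 1] - a[1]) * ab[1] + (G[, 2] - a[2]) * ab[2] +
            (G[, 3] - a[3]) * ab[3]) / L2
    # interior joints are capped (clamped), terminal ends stay flat
    tc <- t
    if (s > 1L) tc <- pmax(tc, 0)
    if (s < nseg) tc <- pmin(tc, 1)
    valid <- tc >= 0 & tc <= 1
    px <- a[1] + tc * ab[1]; py <- a[2] + tc * ab[2]; pz <- a[3] + tc * ab[3]
    d2 <- (G[, 1] - px)^2 + (G[, 2] - py)^2 + (G[, 3] - pz)^2
    inside <- inside | (valid & d2 <= r^2)
  }
  # flat terminal caps: clip everything beyond the end-node planes
  u1 <- path[2, ] - path[1, ]; u1 <- u1 / sqrt(sum(u1^2))
  uN <- path[nrow(path), ] - path[nrow(path) - 1, ]; uN <- uN / sqrt(sum(uN^2))
  p1 <- (G[, 1] - path[1, 1]) * u1[1] + (G[, 2] - path[1, 2]) * u1[2] +
    (G[, 3] - path[1, 3]) * u1[3]
  pN <- (G[, 1] - path[nrow(path), 1]) * uN[1] +
    (G[, 2] - path[nrow(path), 2]) * uN[2] +
    (G[, 3] - path[nrow(path), 3]) * uN[3]
  inside <- inside & p1 >= 0 & pN <= 0
  sub <- array(vol[ix, iy, iz], dim = c(length(ix), length(iy), length(iz)))
  sub[inside] <- 1
  vol[ix, iy, iz] <- sub
  vol
}
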