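#' Excise in-plane-rotated segments along a filament axis
#'
#' Walks the axis polyline at a fixed step and cuts square boxes centered on
#' it, rotating each so the local axis direction is vertical (second image
#' axis), the standard preparation for averaged filament power spectra.
#'
#' @param image an \code{image_grid}.
#' @param axis_A n x 2 matrix of axis polyline coordinates (Angstrom,
#'   relative to the image center; columns x, z).
#' @param box_A box side length, Angstrom (default 350).
#' @param step_A step between segment centers along the axis, Angstrom
#'   (default 60).
#' @return List of \code{image_grid} segments (equal square size); segments
#'   whose box would leave the image are skipped with a message.
#' @export
excise_segments <- function(image, axis_A, box_A = 350, step_A = 60) {
  stopifnot(inherits(image, "image_grid"))
  axis_A <- as.matrix(axis_A)
  if (ncol(axis_A) != 2L || nrow(axis_A) < 2L) {
    stop("axis_A must be an n x 2 polyline with n >= 2")
  }
  px <- image$pixel_A
  box_px <- as.integer(round(box_A / px))

  seg <- diff(axis_A)
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  s_pos <- seq(0, total, by = step_A)

  centers <- matrix(NA_real_, length(s_pos), 2)
  tangents <- matrix(NA_real_, length(s_pos), 2)
  for (k in seq_along(s_pos)) {
    i <- findInterval(s_pos[k], cum, rightmost.closed = TRUE)
    i <- min(max(i, 1L), nrow(seg))
    f <- (s_pos[k] - cum[i]) / seg_len[i]
    centers[k, ] <- axis_A[i, ] + f * seg[i, ]
    tangents[k, ] <- seg[i, ] / seg_len[i]
  }

  c1 <- fft_center(nrow(image$values))
  c2 <- fft_center(ncol(image$values))
  half <- (box_px - 1) / 2
  u <- seq(-half, half) * px   # box-local axes, Angstrom
  grid <- expand.grid(r = u, z = u)

  out <- list()
  skipped <- 0L
  for (k in seq_along(s_pos)) {
    tx <- tangents[k, 1]; tz <- tangents[k, 2]
    # rotate the box so its +z axis maps onto the local tangent
    gx <- centers[k, 1] + grid$r * tz + grid$z * tx
    gz <- centers[k, 2] - grid$r * tx + grid$z * tz
    ri <- gx / px + c1
    ci <- gz / px + c2
    if (min(ri) < 1 || max(ri) > nrow(image$values) ||
        min(ci) < 1 || max(ci) > ncol(image$values)) {
      skipped <- skipped + 1L
      next
    }
    vals <- matrix(bilinear_sample(image$values, ri, ci), box_px, box_px)
    out[[length(out) + 1L]] <- image_grid(vals, px)
  }
  if (skipped > 0L) {
    message(sprintf("excise_segments: %d segment(s) skipped at image bounds",
                    skipped))
  }
  out
}

#' Averaged power spectrum of filament segments
#'
#' |DFT|^2, origin centered, averaged over segments, with reciprocal
#' calibration 1/(n * pixel) per Fourier pixel. The result is
#' Friedel-symmetric (real input).
#'
#' @param segments an \code{image_grid} or list of equal-sized square
#'   \code{image_grid}s.
#' @param taper fraction of the box edge softened by a cosine taper before
#'   the transform (suppresses box-edge ringing; 0 disables).
#' @return A \code{power_spectrum} object: \code{values} (matrix, first index
#'   = radial frequency R, second = axial frequency Z), \code{pixel_A},
#'   \code{fourier_px} (1/Angstrom per Fourier pixel).
#' @export
power_spectrum <- function(segments, taper = 0.1) {
  if (inherits(segments, "image_grid")) segments <- list(segments)
  if (!length(segments)) stop("no segments supplied")
  dims <- vapply(segments, function(s) dim(s$values), integer(2))
  if (any(dims != dims[1, 1])) stop("segments must be square and equal-sized")
  n <- dims[1, 1]
  px <- segments[[1]]$pixel_A
  w <- if (taper > 0) tukey_window(n, taper) else rep(1, n)
  W <- outer(w, w)
  acc <- matrix(0, n, n)
  for (s in segments) acc <- acc + Mod(fft(s$values * W))^2
  acc <- fftshift2(acc / length(segments))
  structure(list(values = acc, pixel_A = px, n = n,
                 fourier_px = 1 / (n * px)),
            class = "power_spectrum")
}

tukey_window <- function(n, alpha) {
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- x < alpha / 2
  hi <- x > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - x[hi]) / alpha - 1)))
  w
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("power_spectrum: %d x %d, %.4g A/px (%.4g 1/A per Fourier px)\n",
              x$n, x$n, x$pixel_A, x$fourier_px))
  invisible(x)
}

#' @export
plot.power_spectrum <- function(x, gamma = 0.25, ...) {
  v <- x$values^gamma
  f <- freq_axis(x$n) / x$pixel_A
  graphics::image(f, f, v, col = grDevices::gray.colors(256),
                  xlab = "R (1/A)", ylab = "Z (1/A)", ...)
  invisible(x)
}

#' Detect layer lines in a power spectrum
#'
#' Scans axial-frequency rows of the upper half plane; a row is a candidate
#' when its background-subtracted maximum exceeds \code{min_snr} times the
#' row noise. The median/MAD background model is evaluated on log power:
#' raw power values are exponentially distributed under noise, and on the
#' log scale the row maximum of pure noise stays within a few MADs of the
#' median, giving a usable false-positive control. Adjacent candidate rows
#' are merged and the height refined by parabolic interpolation.
#'
#' @param spectrum a \code{power_spectrum}.
#' @param min_snr detection threshold in row-noise units (default 3).
#' @param z_exclusion_px rows within this many Fourier pixels of the equator
#'   are excluded (default 1).
#' @param r_exclusion_px columns within this many Fourier pixels of the
#'   meridian are ignored when scoring a row (suppresses the axial streak of
#'   the box transform; default 2).
#' @return Data frame of peaks: \code{z_height} (1/Angstrom, >= 0),
#'   \code{r_position} (1/Angstrom, unsigned, sub-pixel), \code{amplitude},
#'   \code{snr}. Empty when nothing exceeds the threshold.
#' @export
detect_layer_lines <- function(spectrum, min_snr = 3, z_exclusion_px = 1,
                               r_exclusion_px = 2) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  v <- spectrum$values
  n <- spectrum$n
  cz <- fft_center(n); cr <- fft_center(n)
  rcols <- setdiff(seq_len(n), seq.int(cr - r_exclusion_px, cr + r_exclusion_px))
  rows <- seq.int(cz + max(1L, as.integer(z_exclusion_px)) + 0L, n)
  rows <- rows[rows > cz + z_exclusion_px]

  stat <- t(vapply(rows, function(iz) {
    row <- v[rcols, iz]
    lrow <- log(pmax(row, 1e-300))
    bg <- median(lrow)
    noise <- mad(lrow)
    if (noise <= 0) noise <- sd(lrow)
    if (!is.finite(noise) || noise <= 0) noise <- 1e-12
    im <- which.max(row)
    c(snr = (lrow[im] - bg) / noise, amp = row[im], col = rcols[im])
  }, numeric(3)))

  hit <- stat[, "snr"] >= min_snr
  if (!any(hit)) {
    return(data.frame(z_height = numeric(0), r_position = numeric(0),
                      amplitude = numeric(0), snr = numeric(0)))
  }

  fpx <- spectrum$fourier_px
  # profile of row maxima over all rows, for peak picking and interpolation
  rowmax <- apply(v[rcols, , drop = FALSE], 2, max)
  # a hit row is a distinct layer line only at a local maximum of the
  # row-amplitude profile (adjacent rows of the same line are absorbed)
  amp_prof <- rowmax[rows]
  nprof <- length(amp_prof)
  left <- c(-Inf, amp_prof[-nprof])
  right <- c(amp_prof[-1], -Inf)
  is_peak <- hit & amp_prof >= left & amp_prof > right

  peaks <- lapply(which(is_peak), function(k) {
    iz <- rows[k]
    ic <- stat[k, "col"]
    # sub-pixel Z via parabola through the peak column at (iz-1, iz, iz+1)
    zsub <- iz
    if (iz > 1 && iz < n) {
      y <- log(pmax(v[ic, (iz - 1):(iz + 1)], 1e-300))
      den <- y[1] - 2 * y[2] + y[3]
      if (is.finite(den) && den < 0) {
        zsub <- iz + 0.5 * (y[1] - y[3]) / den
      }
    }
    # sub-pixel R on the peak row
    rsub <- ic
    if (ic > 1 && ic < n) {
      y <- log(pmax(v[(ic - 1):(ic + 1), iz], 1e-300))
      den <- y[1] - 2 * y[2] + y[3]
      if (is.finite(den) && den < 0) rsub <- ic + 0.5 * (y[1] - y[3]) / den
    }
    data.frame(z_height = (zsub - cz) * fpx,
               r_position = abs(rsub - cr) * fpx,
               amplitude = stat[k, "amp"],
               snr = stat[k, "snr"])
  })
  out <- do.call(rbind, peaks)
  rownames(out) <- NULL
  out[order(out$z_height), , drop = FALSE]
}

# first maximum of the Bessel function J_n, used to predict the radial
# position of a layer-line peak for a helix of given radius
bessel_first_max <- function(n) {
  n <- abs(n)
  if (n == 0) return(0)
  lo <- max(n * 0.8, 1e-3); hi <- n + 3 * n^(1/3) + 3
  opt <- optimize(function(x) -besselJ(x, n), c(lo, hi))
  opt$minimum
}

#' Index layer-line peaks to candidate helical symmetries
#'
#' Searches a (pitch, rise) lattice; each candidate predicts layer-line
#' heights Z = n/P + m/p (n restricted to multiples of the strand count) and
#' each observed peak is assigned to its nearest prediction. Candidates are
#' ranked by height residual, then by the largest implied |Bessel order|
#' (low-order solutions preferred). When the filament radius is supplied,
#' the radial peak positions are compared with the first maximum of the
#' corresponding Bessel function and the combined residual is used, which
#' separates an s-start lattice from its 1-start alias. The winning
#' assignment is refined by linear least squares in (1/P, 1/p).
#'
#' @param peaks data frame from \code{\link{detect_layer_lines}} (>= 2 rows).
#' @param pitch_bounds numeric c(lo, hi), Angstrom.
#' @param rise_bounds numeric c(lo, hi), Angstrom.
#' @param pitch_step,rise_step search steps, Angstrom.
#' @param n_starts strand counts to consider (integer vector).
#' @param radius_A filament (motif) radius for radial scoring, or NULL.
#' @param n_max,m_max enumeration bounds for the predicted lines.
#' @param tol_A_inv residual tolerance; candidates above it are dropped
#'   (default half a Fourier pixel is a sensible choice, pass it explicitly).
#' @param top_k number of candidates returned.
#' @param max_peaks strongest-by-amplitude peaks used (weak trailing peaks
#'   near the noise floor carry little indexing information).
#' @param min_rel_amplitude peaks weaker than this fraction of the strongest
#'   peak are discarded before indexing.
#' @return Data frame of candidates: \code{pitch_A}, \code{rise_A},
#'   \code{units_per_turn}, \code{n_starts}, \code{residual} (RMS Z error,
#'   1/Angstrom), \code{radial_residual}, \code{max_order}, ranked best
#'   first. Attribute \code{"assignment"} holds the (n, m) table of the best
#'   candidate.
#' @export
index_candidates <- function(peaks, pitch_bounds, rise_bounds,
                             pitch_step = 0.5, rise_step = 0.05,
                             n_starts = 1:3, radius_A = NULL,
                             n_max = 16L, m_max = 1L, tol_A_inv = Inf,
                             top_k = 10L, max_peaks = 12L,
                             min_rel_amplitude = 0.002) {
  if (nrow(peaks) < 2L) stop("at least 2 peaks are required for indexing")
  if (!is.null(peaks$amplitude)) {
    strong <- peaks$amplitude >= min_rel_amplitude * max(peaks$amplitude)
    if (sum(strong) >= 2L) peaks <- peaks[strong, , drop = FALSE]
  }
  if (nrow(peaks) > max_peaks) {
    keep <- order(-peaks$amplitude)[seq_len(max_peaks)]
    peaks <- peaks[sort(keep), , drop = FALSE]
  }
  zobs <- peaks$z_height
  robs <- peaks$r_position
  # strong lines are measured better: weight residuals by root amplitude
  w <- if (!is.null(peaks$amplitude)) sqrt(pmax(peaks$amplitude, 0)) else
    rep(1, length(zobs))
  w <- w / sum(w)
  pitches <- seq(pitch_bounds[1], pitch_bounds[2], by = pitch_step)
  rises <- seq(rise_bounds[1], rise_bounds[2], by = rise_step)

  cand <- list()
  for (s in n_starts) {
    ns <- seq.int(-n_max, n_max)
    ns <- ns[ns %% s == 0]
    ms <- seq.int(-m_max, m_max)
    nm <- expand.grid(n = ns, m = ms)
    rad_pred <- if (!is.null(radius_A)) {
      vapply(nm$n, function(n) bessel_first_max(n) / (2 * pi * radius_A),
             numeric(1))
    } else NULL
    for (P in pitches) for (p in rises) {
      zpred <- nm$n / P + nm$m / p
      keep <- zpred >= -1e-12
      zp <- zpred[keep]; nn <- nm$n[keep]; mm <- nm$m[keep]
      rp <- if (!is.null(rad_pred)) rad_pred[keep] else NULL
      # nearest prediction per observed peak (radial term breaks Z-aliases)
      dz <- abs(outer(zobs, zp, "-"))
      score_m <- dz
      if (!is.null(rp)) score_m <- dz + 0.5 * abs(outer(robs, rp, "-"))
      pick <- apply(score_m, 1, which.min)
      dzb <- dz[cbind(seq_along(zobs), pick)]
      resid <- sqrt(mean(dzb^2))
      resid_w <- sqrt(sum(w * dzb^2))
      rres <- rres_w <- NA_real_
      if (!is.null(rp)) {
        drb <- robs - rp[pick]
        # meridional (n = 0) peaks sit inside the masked axial band: their
        # radial position carries no information; cap outliers so a single
        # stray peak cannot dominate the score
        drb[nn[pick] == 0L] <- 0
        drb <- pmin(abs(drb), 0.02)
        rres <- sqrt(mean(drb^2))
        rres_w <- sqrt(sum(w * drb^2))
      }
      cand[[length(cand) + 1L]] <- list(
        P = P, p = p, s = s, resid = resid, rres = rres,
        resid_w = resid_w, rres_w = rres_w,
        max_order = max(abs(nn[pick])),
        n = nn[pick], m = mm[pick])
    }
  }

  total <- vapply(cand, function(cc)
    cc$resid_w + if (is.na(cc$rres_w)) 0 else 0.5 * cc$rres_w, numeric(1))
  ord <- order(total, vapply(cand, `[[`, numeric(1), "resid"),
               vapply(cand, `[[`, numeric(1), "max_order"))
  cand <- cand[ord]

  rows <- lapply(cand[seq_len(min(top_k, length(cand)))], function(cc) {
    # refine (1/P, 1/p) by least squares on the assignment
    P <- cc$P; p <- cc$p
    if (length(unique(cc$n)) > 1L && length(unique(cc$m)) > 1L) {
      fit <- tryCatch(lm(zobs ~ 0 + cc$n + cc$m, weights = w),
                      error = function(e) NULL)
      if (!is.null(fit)) {
        ab <- coef(fit)
        if (all(is.finite(ab)) && ab[1] > 0 && ab[2] > 0) {
          P <- 1 / ab[1]; p <- 1 / ab[2]
        }
      }
    }
    data.frame(pitch_A = P, rise_A = p, units_per_turn = P / p,
               n_starts = cc$s, residual = cc$resid,
               radial_residual = cc$rres, max_order = cc$max_order)
  })
  out <- do.call(rbind, rows)
  out <- out[out$residual <= tol_A_inv, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "assignment") <- data.frame(z_height = zobs,
                                        n = cand[[1]]$n, m = cand[[1]]$m)
  out
}

#' Symmetry determination by power-spectrum cross-correlation grid search
#'
#' For every node of a (pitch, units-per-turn) grid a model spectrum is
#' simulated and compared with the target by normalized cross-correlation
#' with the equator masked; the argmax is returned together with the full
#' score surface. Ties are broken toward lower units per turn.
#'
#' @param target a \code{power_spectrum}.
#' @param pitch_grid numeric vector of pitches, Angstrom.
#' @param upt_grid numeric vector of units-per-turn values.
#' @param simulator function(pitch_A, units_per_turn) returning a
#'   \code{power_spectrum} of the same size as \code{target}.
#' @param equator_mask_px half-width of the masked equatorial band in
#'   Fourier pixels (default 2).
#' @param gamma power-compression exponent applied to both spectra before
#'   correlating (default 0.25); compressing the dynamic range lets the
#'   weaker high-order layer lines contribute to the score instead of the
#'   few strongest lines dominating it.
#' @return List with \code{pitch_A}, \code{units_per_turn}, \code{score}, and
#'   \code{surface} (matrix of scores, pitches x upt values).
#' @export
grid_search_symmetry <- function(target, pitch_grid, upt_grid, simulator,
                                 equator_mask_px = 2, gamma = 0.25) {
  stopifnot(inherits(target, "power_spectrum"))
  if (!length(pitch_grid) || !length(upt_grid)) stop("empty search grid")
  n <- target$n
  cz <- fft_center(n)
  mask <- rep(TRUE, n)
  mask[seq.int(max(1, cz - equator_mask_px), min(n, cz + equator_mask_px))] <- FALSE
  tv <- target$values[, mask]^gamma
  tv <- tv - mean(tv)
  tnorm <- sqrt(sum(tv^2))

  surface <- matrix(NA_real_, length(pitch_grid), length(upt_grid),
                    dimnames = list(signif(pitch_grid, 6), signif(upt_grid, 6)))
  for (i in seq_along(pitch_grid)) for (j in seq_along(upt_grid)) {
    sim <- simulator(pitch_grid[i], upt_grid[j])
    sv <- sim$values[, mask]^gamma
    sv <- sv - mean(sv)
    surface[i, j] <- sum(tv * sv) / (tnorm * sqrt(sum(sv^2)))
  }
  best <- which(surface == max(surface), arr.ind = TRUE)
  best <- best[order(upt_grid[best[, 2]]), , drop = FALSE][1, ]
  list(pitch_A = pitch_grid[best[1]], units_per_turn = upt_grid[best[2]],
       score = surface[best[1], best[2]], surface = surface)
}
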