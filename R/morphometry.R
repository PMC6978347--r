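#' Threshold a tomogram into a binary filament mask
#'
#' @param tomogram a \code{volume_grid} (or bare array).
#' @param method "otsu" (between-class variance maximization on a 256-bin
#'   histogram), "midpoint" (Otsu followed by relocation to the midpoint of
#'   the filament-interior plateau and the background level, which places
#'   the boundary of a blurred edge at its half-height), or "fixed".
#' @param value threshold for \code{method = "fixed"}.
#' @param dark_foreground set TRUE when filaments are darker than background
#'   (black-on-white data); the mask is taken below the threshold.
#' @return Logical array mask (TRUE = filament), with the threshold used in
#'   attribute \code{"threshold"}.
#' @export
threshold_volume <- function(tomogram, method = c("otsu", "midpoint", "fixed"),
                             value = NULL, dark_foreground = FALSE) {
  method <- match.arg(method)
  v <- if (inherits(tomogram, "volume_grid")) tomogram$values else tomogram
  if (dark_foreground) v <- -v
  if (method %in% c("otsu", "midpoint")) {
    if (max(v) == min(v)) {
      stop("constant volume: otsu is undefined, use method = 'fixed'")
    }
    thr <- otsu_threshold(as.vector(v))
    if (method == "midpoint") {
      m0 <- array(v > thr, dim = dim(v))
      edt <- cpp_edt3d(m0, dim(v))
      deep <- edt >= 3
      plateau <- if (any(deep)) median(v[deep]) else median(v[m0])
      bg <- median(v[!m0])
      thr <- (plateau + bg) / 2
    }
  } else {
    if (is.null(value)) stop("method = 'fixed' requires a value")
    thr <- if (dark_foreground) -value else value
  }
  m <- array(v > thr, dim = dim(v))
  attr(m, "threshold") <- if (dark_foreground) -thr else thr
  m
}

# Otsu's threshold on a 256-bin histogram
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  # ties (plateaus between well-separated modes): take the plateau center
  k <- round(mean(which(sigma_b >= max(sigma_b) - 1e-12 * abs(max(sigma_b)))))
  br[k + 1L]
}

#' Label connected components of a binary volume
#'
#' 26-connectivity; components below \code{min_voxels} are removed. Labels
#' are deterministic: sorted by size (descending), ties by first voxel
#' index.
#'
#' @param mask logical 3D array.
#' @param min_voxels smallest component kept (default 1).
#' @return Integer array of labels (0 = background), with attribute
#'   \code{"sizes"} giving voxel counts per label.
#' @export
extract_components <- function(mask, min_voxels = 1L) {
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
  lab <- cpp_label3d(as.logical(mask), dim(mask))
  if (max(lab) == 0L) {
    attr(lab, "sizes") <- integer(0)
    return(lab)
  }
  sizes <- tabulate(lab[lab > 0L])
  first <- vapply(seq_along(sizes), function(l) which.max(lab == l),
                  numeric(1))
  keep <- which(sizes >= min_voxels)
  ord <- keep[order(-sizes[keep], first[keep])]
  relab <- integer(length(sizes))
  relab[ord] <- seq_along(ord)
  out <- array(0L, dim = dim(mask))
  nz <- lab > 0L
  out[nz] <- relab[lab[nz]]
  attr(out, "sizes") <- sizes[ord]
  out
}

#' Skeletonize a filament component and trace its centerline paths
#'
#' Thins the component to a 1-voxel curve skeleton (sequential deletion of
#' simple border points, endpoints preserved), removes side branches shorter
#' than a prune length, splices chains back together across junction
#' clusters that join exactly two retained chains, and returns the remaining
#' simple paths. Paths never span a junction where three or more branches
#' survive pruning. Node coordinates are smoothed with a short moving
#' average before the length is measured (the discrete skeleton zig-zags,
#' inflating step sums); at free ends the path is extended to the mask
#' boundary, measured as the largest projection of nearby mask voxels onto
#' the end tangent (the skeleton of a capped tube stops short of the true
#' filament end).
#'
#' @param mask logical 3D array, one component (or a labeled array plus
#'   \code{label}).
#' @param voxel_nm voxel size in nm.
#' @param label component label when \code{mask} is a labeled array.
#' @param prune_factor side branches shorter than \code{prune_factor} times
#'   the mean mask radius are removed (default 3).
#' @param min_skeleton_voxels components whose skeleton is shorter than this
#'   are discarded as non-elongated blobs (default 3).
#' @return List of traces; each has \code{path} (n x 3 voxel coordinates),
#'   \code{smooth_path}, \code{length_nm}, and \code{end_radii_nm}.
#' @export
skeletonize_and_trace <- function(mask, voxel_nm = 1, label = NULL,
                                  prune_factor = 3,
                                  min_skeleton_voxels = 3L) {
  if (!is.null(label)) mask <- mask == label
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask)) stop("empty component")
  d <- dim(mask)
  edt <- cpp_edt3d(mask, d)
  skel <- cpp_thin3d(mask, d)
  idx <- which(skel)
  if (length(idx) < min_skeleton_voxels) return(list())

  mean_radius <- mean(edt[idx])
  prune_len <- prune_factor * mean_radius  # voxels

  paths <- trace_skeleton_paths(skel, d, prune_len)
  if (!length(paths)) return(list())
  mask_idx <- which(mask, arr.ind = TRUE)

  single <- length(paths) == 1L
  lapply(paths, function(p) {
    sp <- smooth_path(p$path)
    plen <- path_length_vox(sp)
    np <- nrow(p$path)
    ends <- p$path[c(1, np), , drop = FALSE]
    end_r <- edt[ends]
    if (single && plen < 2 * mean_radius) {
      # stubby component: the skeleton is too short for a reliable tangent;
      # measure the extent along the mask's own principal axis instead
      ctr <- colMeans(mask_idx)
      pc1 <- svd(sweep(mask_idx, 2, ctr))$v[, 1]
      pr <- sweep(mask_idx, 2, ctr) %*% pc1
      return(list(path = p$path, smooth_path = sp,
                  length_nm = (max(pr) - min(pr)) * voxel_nm,
                  end_radii_nm = end_r * voxel_nm))
    }
    corr <- 0
    if (np >= 2) for (e in 1:2) {
      if (p$junction_ends[e]) next
      at_start <- e == 1L
      dir <- end_tangent(sp, at_start)
      if (is.null(dir)) next
      endv <- sp[if (at_start) 1L else nrow(sp), ]
      corr <- corr + projection_extension(mask_idx, endv, dir,
                                          r_ball = 2.5 * mean_radius + 2)
    }
    list(path = p$path, smooth_path = sp,
         length_nm = (plen + corr) * voxel_nm,
         end_radii_nm = end_r * voxel_nm)
  })
}

# moving-average smoothing of node coordinates (window w, ends included)
smooth_path <- function(p, w = 5L) {
  np <- nrow(p)
  if (np <= 2L) return(p)
  k <- (w - 1L) %/% 2L
  out <- p
  for (i in seq_len(np)) {
    lo <- max(1L, i - k); hi <- min(np, i + k)
    out[i, ] <- colMeans(p[lo:hi, , drop = FALSE])
  }
  out
}

# outward end tangent from a line fit through the last few nodes; the
# window is kept short so the chord of a curving path does not tilt it
end_tangent <- function(path, at_start, k = 5L) {
  np <- nrow(path)
  if (np < 2L) return(NULL)
  idxs <- if (at_start) seq_len(min(k, np)) else seq(max(1L, np - k + 1L), np)
  seg <- path[idxs, , drop = FALSE]
  ctr <- colMeans(seg)
  sv <- svd(sweep(seg, 2, ctr))
  dir <- sv$v[, 1]
  endv <- path[if (at_start) 1L else np, ]
  s <- sum(dir * (endv - ctr))
  if (s == 0) return(NULL)
  if (s < 0) dir <- -dir
  dir
}

# how far the mask continues beyond the traced end: the largest projection
# onto the outward tangent of mask voxels inside a narrow corridor around
# the tangent line. The corridor keeps far-transverse cap corners out of the
# estimate; those amplify any tilt of the fitted tangent on curved tubes.
projection_extension <- function(mask_idx, end, dir, r_ball,
                                 transverse_max = 1.5) {
  rel <- sweep(mask_idx, 2, end)
  near <- rowSums(rel^2) <= r_ball^2
  if (!any(near)) return(0)
  rel <- rel[near, , drop = FALSE]
  pr <- drop(rel %*% dir)
  transv2 <- rowSums(rel^2) - pr^2
  ok <- transv2 <= transverse_max^2
  if (!any(ok)) return(0)
  max(0, max(pr[ok]))
}

path_length_vox <- function(path) {
  if (nrow(path) < 2L) return(0)
  sum(sqrt(rowSums(diff(path)^2)))
}

# decompose a skeleton into chains and junction clusters, prune short leaf
# branches, splice chains across 2-valent junction clusters
trace_skeleton_paths <- function(skel, d, prune_len) {
  idx <- which(skel)
  coords <- arrayInd(idx, d)
  pos <- array(0L, dim = d)
  pos[idx] <- seq_along(idx)

  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  neighbors <- function(i) {
    nb <- sweep(offs, 2, coords[i, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    p <- pos[nb[ok, , drop = FALSE]]
    p[p > 0L]
  }
  deg <- vapply(seq_along(idx), function(i) length(neighbors(i)), integer(1))
  junction <- deg >= 3L

  sub <- array(FALSE, dim = d)
  sub[idx[!junction]] <- TRUE
  chain_lab_arr <- cpp_label3d(sub, d)
  chain_of <- chain_lab_arr[idx]          # 0 for junction voxels
  nchain <- max(chain_of)
  if (nchain == 0L) {
    # all junction: treat the whole skeleton as one path
    ord <- order_chain(seq_along(idx), coords, neighbors)
    return(list(list(path = coords[ord, , drop = FALSE],
                     junction_ends = c(FALSE, FALSE))))
  }
  jsub <- array(FALSE, dim = d)
  jsub[idx[junction]] <- TRUE
  jc_arr <- cpp_label3d(jsub, d)
  jc_of <- jc_arr[idx]                    # junction cluster id per voxel

  chains <- vector("list", nchain)
  for (cl in seq_len(nchain)) {
    members <- which(chain_of == cl)
    ord <- order_chain(members, coords, neighbors)
    ends <- c(ord[1], ord[length(ord)])
    jadj <- vapply(ends, function(i) {
      nb <- neighbors(i)
      j <- jc_of[nb]
      j <- j[j > 0L]
      if (length(j)) j[1] else 0L
    }, integer(1))
    if (length(members) == 1L) jadj[2] <- 0L  # single voxel: one logical end
    chains[[cl]] <- list(members = ord, jends = jadj)
  }
  chain_len <- function(ch) {
    p <- coords[ch$members, , drop = FALSE]
    path_length_vox(p)
  }

  alive <- rep(TRUE, nchain)
  # iterative pruning of short junction-attached leaf branches
  repeat {
    pruned <- FALSE
    for (cl in which(alive)) {
      ch <- chains[[cl]]
      att <- sum(ch$jends > 0L)
      if (att >= 1L && att < 2L && chain_len(ch) < prune_len) {
        # make sure we do not erase the only chain
        if (sum(alive) > 1L) {
          alive[cl] <- FALSE
          pruned <- TRUE
        }
      }
    }
    if (!pruned) break
  }

  # splice across junction clusters joined to exactly two living chain ends;
  # clusters left with a single chain (all other branches pruned) are
  # absorbed into that chain and the end becomes free
  repeat {
    jc_ids <- unique(unlist(lapply(chains[alive], function(ch)
      ch$jends[ch$jends > 0L])))
    spliced <- FALSE
    for (j in jc_ids) {
      touch <- which(vapply(seq_len(nchain), function(cl)
        alive[cl] && any(chains[[cl]]$jends == j), logical(1)))
      if (length(touch) == 1L &&
          sum(chains[[touch]]$jends == j) == 1L) {
        cha <- chains[[touch]]
        if (cha$jends[1] == j) {
          cha$members <- rev(cha$members); cha$jends <- rev(cha$jends)
        }
        jvox <- which(jc_of == j)
        aend <- coords[cha$members[length(cha$members)], ]
        jord <- jvox[order(rowSums(sweep(coords[jvox, , drop = FALSE], 2,
                                         aend)^2))]
        chains[[touch]] <- list(members = c(cha$members, jord),
                                jends = c(cha$jends[1], 0L))
        spliced <- TRUE
        break
      }
      if (length(touch) != 2L) next
      a <- touch[1]; b <- touch[2]
      cha <- chains[[a]]; chb <- chains[[b]]
      if (sum(cha$jends == j) != 1L || sum(chb$jends == j) != 1L) next
      # orient a with its j-end last, b with its j-end first
      if (cha$jends[1] == j) {
        cha$members <- rev(cha$members); cha$jends <- rev(cha$jends)
      }
      if (chb$jends[2] == j) {
        chb$members <- rev(chb$members); chb$jends <- rev(chb$jends)
      }
      jvox <- which(jc_of == j)
      aend <- coords[cha$members[length(cha$members)], ]
      jord <- jvox[order(rowSums(sweep(coords[jvox, , drop = FALSE], 2,
                                       aend)^2))]
      chains[[a]] <- list(members = c(cha$members, jord, chb$members),
                          jends = c(cha$jends[1], chb$jends[2]))
      alive[b] <- FALSE
      spliced <- TRUE
      break
    }
    if (!spliced) break
  }

  lapply(which(alive), function(cl) {
    ch <- chains[[cl]]
    list(path = coords[ch$members, , drop = FALSE],
         junction_ends = ch$jends > 0L)
  })
}

# order a set of chain-member voxels into a walk from one end
order_chain <- function(members, coords, neighbors) {
  n <- length(members)
  if (n <= 2L) return(members)
  mset <- structure(rep(TRUE, n), names = members)
  deg_in <- vapply(members, function(i) {
    sum(as.character(neighbors(i)) %in% names(mset))
  }, integer(1))
  start <- members[which(deg_in <= 1L)[1]]
  if (is.na(start)) start <- members[1]
  ord <- integer(n)
  visited <- structure(rep(FALSE, n), names = members)
  cur <- start
  for (k in seq_len(n)) {
    ord[k] <- cur
    visited[as.character(cur)] <- TRUE
    nbs <- neighbors(cur)
    nbs <- nbs[as.character(nbs) %in% names(visited)]
    nbs <- nbs[!visited[as.character(nbs)]]
    if (!length(nbs)) break
    if (length(nbs) > 1L) {
      dd <- rowSums(abs(coords[nbs, , drop = FALSE] -
                          matrix(coords[cur, ], length(nbs), 3, byrow = TRUE)))
      nbs <- nbs[order(dd)]
    }
    cur <- nbs[1]
  }
  ord[ord > 0L]
}

#' Width profile of a trace by radial ray casting
#'
#' Per interior node, rays are cast perpendicular to the local (smoothed)
#' centerline tangent in \code{n_rays} directions; each ray records the
#' distance to the mask boundary on both sides and their sum is one diameter
#' sample. The node width is the mean over rays, optionally corrected for
#' the inward bias of a thresholded blurred boundary on a convex tube
#' (a surface blurred with Gaussian sigma recedes by about sigma^2 / width
#' on each side). The mean width is a 10 percent trimmed mean over interior
#' nodes (nodes within two radii of either end are excluded, where cap
#' geometry biases the profile).
#'
#' @param trace a trace from \code{\link{skeletonize_and_trace}}.
#' @param mask the binary mask the trace was extracted from.
#' @param voxel_nm voxel size, nm.
#' @param n_rays number of ray directions per node (default 8).
#' @param blur_sigma_vox blur (voxels) assumed for the convexity
#'   correction; 0 disables the correction.
#' @return List with \code{widths_nm} (per interior node) and
#'   \code{mean_width_nm}.
#' @export
measure_width <- function(trace, mask, voxel_nm = 1, n_rays = 8L,
                          blur_sigma_vox = 0) {
  mask <- array(as.logical(mask), dim = dim(mask))
  d <- dim(mask)
  sp <- if (!is.null(trace$smooth_path)) trace$smooth_path else
    smooth_path(trace$path)
  np <- nrow(sp)
  if (np == 1L) {
    edt <- cpp_edt3d(mask, d)
    w0 <- 2 * max(edt[trace$path], 0.5) * voxel_nm
    return(list(widths_nm = w0, mean_width_nm = w0))
  }

  widths <- rep(NA_real_, np)
  for (i in seq_len(np)) {
    lo <- max(1L, i - 2L); hi <- min(np, i + 2L)
    tang <- sp[hi, ] - sp[lo, ]
    tn <- sqrt(sum(tang^2))
    if (tn == 0) next
    tang <- tang / tn
    # orthonormal frame
    a <- if (abs(tang[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- a - sum(a * tang) * tang; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(tang[2] * e1[3] - tang[3] * e1[2],
            tang[3] * e1[1] - tang[1] * e1[3],
            tang[1] * e1[2] - tang[2] * e1[1])
    dsum <- 0; nray <- 0L
    for (k in seq_len(n_rays)) {
      th <- pi * (k - 1) / n_rays
      u <- cos(th) * e1 + sin(th) * e2
      dpos <- ray_to_boundary(mask, sp[i, ], u, d)
      dneg <- ray_to_boundary(mask, sp[i, ], -u, d)
      if (is.na(dpos) || is.na(dneg)) next
      dsum <- dsum + dpos + dneg
      nray <- nray + 1L
    }
    if (nray > 0L) widths[i] <- dsum / nray
  }
  if (blur_sigma_vox > 0) {
    widths <- widths + 2 * blur_sigma_vox^2 / pmax(widths, 1)
  }
  widths <- widths * voxel_nm

  s_fwd <- c(0, cumsum(sqrt(rowSums(diff(sp)^2))))
  s_rev <- s_fwd[np] - s_fwd
  rbar <- mean(widths, na.rm = TRUE) / (2 * voxel_nm)
  if (!is.finite(rbar)) rbar <- 1
  interior <- s_fwd >= 2 * rbar & s_rev >= 2 * rbar & !is.na(widths)
  if (!any(interior)) interior <- !is.na(widths)
  if (!any(interior)) {
    return(list(widths_nm = numeric(0), mean_width_nm = NA_real_))
  }
  list(widths_nm = widths[interior],
       mean_width_nm = mean(widths[interior], trim = 0.1))
}

# distance along direction u from point p to the first sample outside mask
ray_to_boundary <- function(mask, p, u, d, step = 0.25, max_t = 60) {
  t <- 0
  repeat {
    t2 <- t + step
    pos <- round(p + t2 * u)
    if (any(pos < 1L) || any(pos > d)) return(t)
    if (!mask[matrix(pos, 1)]) return(t + step / 2)
    t <- t2
    if (t > max_t) return(NA_real_)
  }
}

#' Morphometry of all filaments in a tomogram
#'
#' End-to-end pipeline: threshold, component extraction, skeleton tracing,
#' width measurement, summary.
#'
#' @param tomogram a \code{volume_grid} (unit nm).
#' @param min_voxels smallest component analyzed.
#' @param method threshold method, see \code{\link{threshold_volume}}.
#' @param value fixed threshold value.
#' @param smooth_sigma_vox Gaussian pre-smoothing of the volume, in voxels
#'   (default 1.5), which suppresses single-voxel noise speckle before
#'   thresholding; 0 disables.
#' @return A \code{morphometry_summary}: \code{traces} data frame
#'   (trace_id, component, length_nm, mean_width_nm, n_nodes),
#'   \code{mean_length_nm}, \code{sd_length_nm}, \code{mean_width_nm},
#'   \code{sd_width_nm}, \code{n_traces}.
#' @export
tomogram_morphometry <- function(tomogram, min_voxels = 100L,
                                 method = "midpoint", value = NULL,
                                 smooth_sigma_vox = 1.5) {
  stopifnot(inherits(tomogram, "volume_grid"))
  voxel <- tomogram$voxel
  if (smooth_sigma_vox > 0) {
    tomogram <- volume_grid(gauss_smooth3(tomogram$values, smooth_sigma_vox),
                            tomogram$voxel, tomogram$unit)
  }
  mask <- threshold_volume(tomogram, method = method, value = value)
  lab <- extract_components(mask, min_voxels = min_voxels)
  ncomp <- max(lab)
  rows <- list()
  tid <- 0L
  for (cl in seq_len(ncomp)) {
    # work on the component bounding box (thinning cost scales with volume)
    idx <- which(lab == cl, arr.ind = TRUE)
    lo <- pmax(apply(idx, 2, min) - 2L, 1L)
    hi <- pmin(apply(idx, 2, max) + 2L, dim(lab))
    cmask <- lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE] == cl
    cmask <- array(cmask, dim = hi - lo + 1L)
    traces <- skeletonize_and_trace(cmask, voxel_nm = voxel)
    for (tr in traces) {
      tid <- tid + 1L
      w <- measure_width(tr, cmask, voxel_nm = voxel,
                         blur_sigma_vox = smooth_sigma_vox)
      rows[[tid]] <- data.frame(trace_id = tid, component = cl,
                                length_nm = tr$length_nm,
                                mean_width_nm = w$mean_width_nm,
                                n_nodes = nrow(tr$path))
    }
  }
  traces <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trace_id = integer(0), component = integer(0),
               length_nm = numeric(0), mean_width_nm = numeric(0),
               n_nodes = integer(0))
  summarize_traces(traces)
}

#' Summarize a per-trace morphometry table
#'
#' @param traces data frame with \code{length_nm} and \code{mean_width_nm}.
#' @param hist_binwidth_nm histogram bin width, nm.
#' @return A \code{morphometry_summary}.
#' @export
summarize_traces <- function(traces, hist_binwidth_nm = 5) {
  n <- nrow(traces)
  single <- n == 1L
  mk_hist <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) return(NULL)
    br <- seq(0, max(x) + hist_binwidth_nm, by = hist_binwidth_nm)
    graphics::hist(x, breaks = br, plot = FALSE)
  }
  structure(list(
    traces = traces,
    n_traces = n,
    mean_length_nm = if (n) mean(traces$length_nm, na.rm = TRUE) else NA_real_,
    sd_length_nm = if (n > 1) sd(traces$length_nm, na.rm = TRUE) else if (n == 1) 0 else NA_real_,
    mean_width_nm = if (n) mean(traces$mean_width_nm, na.rm = TRUE) else NA_real_,
    sd_width_nm = if (n > 1) sd(traces$mean_width_nm, na.rm = TRUE) else if (n == 1) 0 else NA_real_,
    sd_undefined = single,
    length_hist = mk_hist(traces$length_nm),
    width_hist = mk_hist(traces$mean_width_nm)),
    class = "morphometry_summary")
}

#' @export
print.morphometry_summary <- function(x, ...) {
  cat(sprintf("morphometry_summary: %d trace(s)\n", x$n_traces))
  if (x$n_traces) {
    cat(sprintf("  length: %.3g +/- %.3g nm%s\n", x$mean_length_nm,
                x$sd_length_nm, if (x$sd_undefined) " (SD undefined, single trace)" else ""))
    cat(sprintf("  width:  %.3g +/- %.3g nm\n", x$mean_width_nm, x$sd_width_nm))
  }
  invisible(x)
}
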