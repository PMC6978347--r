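#' Helical symmetry description
#'
#' A helical lattice is described by the screw operation relating consecutive
#' asymmetric units: an axial translation (rise, in Angstrom) and a rotation
#' about the helix axis (twist, in degrees). Point symmetry about the axis
#' (cyclic Cc) and a local two-fold perpendicular to the axis (dihedral, for
#' antiparallel rungs) multiply each asymmetric unit into several copies.
#'
#' Sign convention: the helix axis is +z in a right-handed frame; a negative
#' twist is a left-handed screw when viewed down +z. Twist is stored wrapped
#' into (-180, 180].
#'
#' @param rise_A axial rise per asymmetric unit, Angstrom (> 0).
#' @param twist_deg signed twist per asymmetric unit, degrees (non-zero);
#'   wrapped into (-180, 180].
#' @param axial_cyclic integer c >= 1, cyclic point symmetry Cc about the axis.
#' @param dihedral logical; TRUE when a rung propagates antiparallel, adding a
#'   copy related by a two-fold axis perpendicular to the helix axis.
#' @param monomers_per_asu integer >= 1, monomers grouped into one asymmetric
#'   unit (equivalent notations regroup k consecutive subunits).
#' @return An object of class \code{helical_symmetry}.
#' @examples
#' atnbr1_s <- helical_symmetry(5.905, -31.17)
#' units_per_turn(atnbr1_s$twist_deg)
#' pitch_of(atnbr1_s$rise_A, atnbr1_s$twist_deg)
#' @export
helical_symmetry <- function(rise_A, twist_deg, axial_cyclic = 1L,
                             dihedral = FALSE, monomers_per_asu = 1L) {
  if (!is.numeric(rise_A) || length(rise_A) != 1L || !is.finite(rise_A) ||
      rise_A <= 0) {
    stop("rise_A must be a single positive finite number (Angstrom)")
  }
  if (!is.numeric(twist_deg) || length(twist_deg) != 1L ||
      !is.finite(twist_deg) || twist_deg == 0) {
    stop("twist_deg must be a single non-zero finite angle (degrees)")
  }
  axial_cyclic <- as.integer(axial_cyclic)
  if (is.na(axial_cyclic) || axial_cyclic < 1L) {
    stop("axial_cyclic must be an integer >= 1")
  }
  monomers_per_asu <- as.integer(monomers_per_asu)
  if (is.na(monomers_per_asu) || monomers_per_asu < 1L) {
    stop("monomers_per_asu must be an integer >= 1")
  }
  structure(
    list(rise_A = rise_A, twist_deg = wrap_angle(twist_deg),
         axial_cyclic = axial_cyclic, dihedral = isTRUE(dihedral),
         monomers_per_asu = monomers_per_asu),
    class = "helical_symmetry")
}

#' @export
print.helical_symmetry <- function(x, ...) {
  cat(sprintf("Helical symmetry: rise %.4g A, twist %.4g deg (C%d%s, %d monomer%s/asu)\n",
              x$rise_A, x$twist_deg, x$axial_cyclic,
              if (x$dihedral) ", dihedral" else "",
              x$monomers_per_asu, if (x$monomers_per_asu > 1L) "s" else ""))
  cat(sprintf("  pitch %.4g A, %.4g units/turn, %s-handed\n",
              pitch_of(x$rise_A, x$twist_deg), units_per_turn(x$twist_deg),
              if (x$twist_deg < 0) "left" else "right"))
  invisible(x)
}

#' Wrap an angle into (-180, 180]
#'
#' Ties at -180 map to +180.
#'
#' @param deg angle(s) in degrees.
#' @return Wrapped angle(s).
#' @export
wrap_angle <- function(deg) {
  w <- deg - 360 * floor(deg / 360 + 0.5)   # [-180, 180)
  w[w == -180] <- 180
  w
}

#' Subunits per helical turn
#'
#' U = 360 / |twist|; independent of handedness.
#'
#' @param twist_deg signed twist per subunit, degrees (non-zero).
#' @return Positive number of subunits per 360-degree turn.
#' @export
units_per_turn <- function(twist_deg) {
  if (any(!is.finite(twist_deg)) || any(twist_deg == 0)) {
    stop("twist_deg must be finite and non-zero")
  }
  360 / abs(twist_deg)
}

#' Helical pitch
#'
#' Axial distance per full turn of one strand: P = rise * 360 / |twist|.
#'
#' @param rise_A rise per subunit, Angstrom (> 0).
#' @param twist_deg signed twist per subunit, degrees (non-zero).
#' @return Pitch in Angstrom.
#' @export
pitch_of <- function(rise_A, twist_deg) {
  if (any(!is.finite(rise_A)) || any(rise_A <= 0)) {
    stop("rise_A must be positive and finite")
  }
  rise_A * units_per_turn(twist_deg)
}

#' Lattice description (pitch, units per turn) of a helical symmetry
#'
#' @param sym a \code{helical_symmetry}.
#' @return List with \code{pitch_A}, \code{units_per_turn}, \code{n_starts}
#'   (the axial cyclic order: a Cc helix is a c-start lattice), and
#'   \code{handedness}.
#' @export
to_lattice <- function(sym) {
  stopifnot(inherits(sym, "helical_symmetry"))
  list(pitch_A = pitch_of(sym$rise_A, sym$twist_deg),
       units_per_turn = units_per_turn(sym$twist_deg),
       n_starts = sym$axial_cyclic,
       handedness = if (sym$twist_deg < 0) "left" else "right")
}

#' Equivalent helical-symmetry notation
#'
#' Regroups k consecutive subunits (with an optional point-group phase j) into
#' one asymmetric unit: rise' = k * rise, twist' = wrap(k * twist + j * 360/c).
#' Every choice of (k, j) generates the identical point set when the composite
#' asymmetric unit (the k consecutive subunits) is expanded, which is how a
#' one-monomer and a two-monomer notation of the same lattice coexist.
#'
#' @param sym a \code{helical_symmetry}.
#' @param k integer >= 1, subunits grouped per new asymmetric unit.
#' @param j integer point-group phase, 0 <= j < axial_cyclic.
#' @return A new \code{helical_symmetry}.
#' @examples
#' # p62 L-type: one-monomer (4.787 A, 77.29 deg, C2) regrouped as two monomers
#' equivalent_description(helical_symmetry(4.787, 77.29, axial_cyclic = 2), 2, 1)
#' @export
equivalent_description <- function(sym, k = 1L, j = 0L) {
  stopifnot(inherits(sym, "helical_symmetry"))
  k <- as.integer(k); j <- as.integer(j)
  if (is.na(k) || k < 1L) stop("k must be an integer >= 1")
  if (is.na(j) || j < 0L || j >= sym$axial_cyclic) {
    stop("j must satisfy 0 <= j < axial_cyclic")
  }
  helical_symmetry(rise_A = k * sym$rise_A,
                   twist_deg = wrap_angle(k * sym$twist_deg +
                                            j * 360 / sym$axial_cyclic),
                   axial_cyclic = sym$axial_cyclic,
                   dihedral = sym$dihedral,
                   monomers_per_asu = k * sym$monomers_per_asu)
}

#' Rationalize units-per-turn as an integer helix
#'
#' Finds integers u (subunits) and t (turns), gcd(u, t) = 1, with t <=
#' max_turns minimizing |u/t - U| (the best bounded-denominator rational
#' approximation, which is always a convergent or semiconvergent of the
#' continued fraction of U). Ties are broken by smaller t, then smaller u.
#'
#' @param U subunits per turn (> 1).
#' @param max_turns largest allowed number of turns t (>= 1).
#' @return List with integers \code{u}, \code{t} and the achieved
#'   \code{error} = |u/t - U|, of class \code{integer_helix}.
#' @export
rationalize <- function(U, max_turns) {
  if (!is.numeric(U) || length(U) != 1L || !is.finite(U) || U <= 1) {
    stop("U must be a single finite number > 1")
  }
  max_turns <- as.integer(max_turns)
  if (is.na(max_turns) || max_turns < 1L) stop("max_turns must be >= 1")
  best <- NULL
  for (t in seq_len(max_turns)) {
    u <- round(U * t)
    if (u < 1) u <- 1
    err <- abs(u / t - U)
    if (is.null(best) || err < best$error - 1e-15) {
      g <- gcd_int(u, t)
      best <- list(u = as.integer(u / g), t = as.integer(t / g), error = err)
    }
  }
  structure(best, class = "integer_helix")
}

#' @export
print.integer_helix <- function(x, ...) {
  cat(sprintf("Integer helix: %d subunits in %d turns (u/t = %.6g, error %.3g)\n",
              x$u, x$t, x$u / x$t, x$error))
  invisible(x)
}

gcd_int <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { tmp <- a %% b; a <- b; b <- tmp }
  max(a, 1)
}

#' Allowed Bessel orders on a layer line
#'
#' For a helix with u subunits in t turns the diffraction selection rule is
#' l = t n + u m (l layer-line index, n Bessel order, m any integer). Returns
#' every n with |n| <= n_max for which some integer m satisfies the rule.
#'
#' @param helix an \code{integer_helix} (or list with integers u, t).
#' @param l integer layer-line index.
#' @param n_max largest |n| considered (>= 0).
#' @return Sorted integer vector of allowed Bessel orders.
#' @export
selection_orders <- function(helix, l, n_max) {
  u <- as.integer(helix$u); t <- as.integer(helix$t)
  l <- as.integer(l); n_max <- as.integer(n_max)
  if (is.na(n_max) || n_max < 0L) stop("n_max must be >= 0")
  n <- seq.int(-n_max, n_max)
  ok <- (l - t * n) %% u == 0L
  sort(n[ok])
}

#' Reciprocal heights of helical layer lines
#'
#' Layer lines of a helix with pitch P and rise p sit at reciprocal heights
#' Z = n/P + m/p. Enumerates all (n, m) with |n| <= n_max, |m| <= m_max and
#' 0 <= Z <= z_max; coincident heights are merged with all contributing (n, m)
#' recorded. With axial point symmetry Cc only Bessel orders divisible by c
#' survive, and the enumeration honors that.
#'
#' @param sym a \code{helical_symmetry}.
#' @param n_max,m_max enumeration bounds for Bessel order n and meridional
#'   index m.
#' @param z_max largest reciprocal height retained, 1/Angstrom (> 0).
#' @param tol heights closer than this (1/Angstrom) are merged.
#' @return Data frame with columns \code{Z} (1/Angstrom), \code{n}, \code{m}
#'   (comma-collapsed strings when several orders coincide), sorted by Z.
#' @export
layer_line_heights <- function(sym, n_max = 3L, m_max = 2L, z_max,
                               tol = 1e-9) {
  stopifnot(inherits(sym, "helical_symmetry"))
  if (!is.numeric(z_max) || z_max <= 0) stop("z_max must be > 0")
  P <- pitch_of(sym$rise_A, sym$twist_deg)
  p <- sym$rise_A
  ns <- seq.int(-n_max, n_max)
  ns <- ns[ns %% sym$axial_cyclic == 0L]
  grid <- expand.grid(n = ns, m = seq.int(-m_max, m_max))
  grid$Z <- grid$n / P + grid$m / p
  grid <- grid[grid$Z >= -tol & grid$Z <= z_max + tol, , drop = FALSE]
  grid$Z[grid$Z < 0] <- 0
  grid <- grid[order(grid$Z, abs(grid$n)), , drop = FALSE]
  if (nrow(grid) == 0L) {
    return(data.frame(Z = numeric(0), n = character(0), m = character(0),
                      stringsAsFactors = FALSE))
  }
  key <- cumsum(c(TRUE, diff(grid$Z) > tol))
  out <- do.call(rbind, lapply(split(grid, key), function(g) {
    data.frame(Z = g$Z[1],
               n = paste(g$n, collapse = ","),
               m = paste(g$m, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Expand an asymmetric unit along a helical lattice
#'
#' Subunit i (i = start_index, ..., start_index + count - 1) is obtained by
#' rotating the asymmetric-unit points by i * twist about z and translating
#' by i * rise along z. For axial_cyclic c > 1, c copies rotated by 360/c are
#' generated per subunit; for dihedral symmetry an additional copy related by
#' a two-fold axis along x (azimuth 0) is added for every copy. Cylindrical
#' radii are preserved exactly (screw operations are isometries).
#'
#' @param sym a \code{helical_symmetry}.
#' @param asu_points numeric matrix n x 3 (columns x, y, z, Angstrom).
#' @param count number of subunits generated (>= 1).
#' @param start_index index of the first subunit (default 0).
#' @return Data frame with columns \code{subunit}, \code{copy} (point-group
#'   copy id), \code{x}, \code{y}, \code{z}.
#' @export
expand_symmetry <- function(sym, asu_points, count, start_index = 0L) {
  stopifnot(inherits(sym, "helical_symmetry"))
  asu_points <- as.matrix(asu_points)
  if (nrow(asu_points) == 0L) stop("asu_points must contain at least one point")
  if (ncol(asu_points) != 3L) stop("asu_points must be an n x 3 matrix")
  count <- as.integer(count)
  if (is.na(count) || count < 1L) stop("count must be >= 1")
  start_index <- as.integer(start_index)

  c_ord <- sym$axial_cyclic
  copies <- list()
  idx <- 0L
  for (jc in seq_len(c_ord) - 1L) {
    pts <- rot_z(asu_points, jc * 360 / c_ord)
    copies[[length(copies) + 1L]] <- list(id = idx, pts = pts)
    idx <- idx + 1L
    if (sym$dihedral) {
      # two-fold about x: (x, y, z) -> (x, -y, -z)
      dpts <- pts %*% diag(c(1, -1, -1))
      copies[[length(copies) + 1L]] <- list(id = idx, pts = dpts)
      idx <- idx + 1L
    }
  }

  out <- vector("list", count * length(copies))
  k <- 1L
  for (i in seq.int(start_index, start_index + count - 1L)) {
    ang <- i * sym$twist_deg
    dz <- i * sym$rise_A
    for (cp in copies) {
      pts <- rot_z(cp$pts, ang)
      pts[, 3] <- pts[, 3] + dz
      out[[k]] <- data.frame(subunit = i, copy = cp$id,
                             x = pts[, 1], y = pts[, 2], z = pts[, 3])
      k <- k + 1L
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

rot_z <- function(pts, deg) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), 0,
                -sin(th), cos(th), 0,
                0, 0, 1), 3, 3)
  pts %*% R
}

#' Round half-up to a number of decimals (reporting layer only)
#'
#' Matches the round-half-up convention of printed tables; used when quoting
#' values at printed precision, never inside computations.
#'
#' @param x numeric.
#' @param digits decimals.
#' @return Rounded numeric.
#' @export
report_round <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Read or write helical symmetry as JSON
#'
#' Serialized as a record \code{{rise_A, twist_deg, axial_cyclic, dihedral,
#' monomers_per_asu}}.
#'
#' @param sym a \code{helical_symmetry}.
#' @param path file path.
#' @return \code{read_symmetry_json} returns a \code{helical_symmetry};
#'   \code{write_symmetry_json} returns \code{path} invisibly.
#' @export
write_symmetry_json <- function(sym, path) {
  stopifnot(inherits(sym, "helical_symmetry"))
  jsonlite::write_json(unclass(sym), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_symmetry_json
#' @export
read_symmetry_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  helical_symmetry(x$rise_A, x$twist_deg, x$axial_cyclic, x$dihedral,
                   x$monomers_per_asu)
}
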