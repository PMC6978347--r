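# Shared fixtures built in code.

# screw transform of points: rotate by twist about z, translate rise along z
screw_pts <- function(pts, twist_deg, rise_A, k = 1L) {
  th <- k * twist_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  out <- pts %*% R
  out[, 3] <- out[, 3] + k * rise_A
  out
}

# toy arginine-finger asymmetric unit on a U = 11.55 lattice: two donor
# residues (R21/R22 analogs) whose next-subunit copies land next to a
# four-residue acidic cluster, plus one acceptor a full turn up for a
# longitudinal contact
arg_finger_asu <- function(radius = 52) {
  rise <- 5.905
  twist <- -360 / 11.55
  p_r21 <- c(radius, 0, 0)
  p_r22 <- c(radius, 2.5, 1.5)
  q21 <- screw_pts(rbind(p_r21), twist, rise)[1, ]
  q22 <- screw_pts(rbind(p_r22), twist, rise)[1, ]
  q21_turn <- screw_pts(rbind(p_r21), twist, rise, k = 12L)[1, ]
  atoms <- rbind(
    data.frame(chain = "A", resno = 21, resid = "ARG", elety = "NH1",
               x = p_r21[1], y = p_r21[2], z = p_r21[3]),
    data.frame(chain = "A", resno = 22, resid = "ARG", elety = "NH1",
               x = p_r22[1], y = p_r22[2], z = p_r22[3]),
    # acidic cluster positioned where the NEXT subunit's arginines arrive
    data.frame(chain = "A", resno = 69, resid = "ASP", elety = "OD1",
               x = q21[1], y = q21[2], z = q21[3] + 1.5),
    data.frame(chain = "A", resno = 71, resid = "ASP", elety = "OD1",
               x = q21[1], y = q21[2], z = q21[3] - 1.5),
    data.frame(chain = "A", resno = 73, resid = "ASP", elety = "OD1",
               x = q22[1], y = q22[2], z = q22[3] + 1.5),
    data.frame(chain = "A", resno = 82, resid = "GLU", elety = "OE1",
               x = q22[1], y = q22[2], z = q22[3] - 1.5),
    # acceptor one full turn up the same strand (longitudinal contact)
    data.frame(chain = "A", resno = 93, resid = "ASP", elety = "OD1",
               x = q21_turn[1], y = q21_turn[2], z = q21_turn[3] - 3.0))
  pb1_structure(atoms)
}

u1155_sym <- function() helical_symmetry(5.905, -360 / 11.55)

# independent brute-force salt-bridge scan (reference oracle)
brute_force_bridges <- function(structure, cutoff = 4.0) {
  a <- structure$atoms
  bas <- a[(a$resid == "ARG" & a$elety %in% c("NH1", "NH2", "NE")) |
             (a$resid == "LYS" & a$elety == "NZ"), , drop = FALSE]
  aci <- a[(a$resid == "ASP" & a$elety %in% c("OD1", "OD2")) |
             (a$resid == "GLU" & a$elety %in% c("OE1", "OE2")), , drop = FALSE]
  hits <- list()
  for (i in seq_len(nrow(bas))) {
    for (j in seq_len(nrow(aci))) {
      dd <- sqrt((bas$x[i] - aci$x[j])^2 + (bas$y[i] - aci$y[j])^2 +
                   (bas$z[i] - aci$z[j])^2)
      if (dd <= cutoff) {
        hits[[length(hits) + 1L]] <- data.frame(
          donor_chain = bas$chain[i], donor_resno = bas$resno[i],
          acceptor_chain = aci$chain[j], acceptor_resno = aci$resno[j],
          dist = dd)
      }
    }
  }
  if (!length(hits)) return(NULL)
  h <- do.call(rbind, hits)
  key <- paste(h$donor_chain, h$donor_resno, h$acceptor_chain,
               h$acceptor_resno)
  agg <- do.call(rbind, lapply(split(h, key), function(g)
    g[which.min(g$dist), , drop = FALSE]))
  agg[order(agg$donor_chain, agg$donor_resno, agg$acceptor_chain,
            agg$acceptor_resno), , drop = FALSE]
}

# straight solid tube mask along a given axis of a 3D array
straight_tube_mask <- function(dims, axis = 3, radius = 5, from, to) {
  m <- array(FALSE, dims)
  ctr <- (dims + 1) / 2
  ax <- setdiff(1:3, axis)
  co <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]),
                              seq_len(dims[3])))
  r2 <- (co[, ax[1]] - ctr[ax[1]])^2 + (co[, ax[2]] - ctr[ax[2]])^2
  sel <- r2 <= radius^2 & co[, axis] >= from & co[, axis] <= to
  m[co[sel, , drop = FALSE]] <- TRUE
  m
}
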