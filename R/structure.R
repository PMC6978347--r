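#' Minimal atomic structure container
#'
#' A flat atom table: chain, residue number, residue name, atom name,
#' element, coordinates (Angstrom) and an optional subunit index assigned by
#' helical expansion. (chain, resno, elety) triples must be unique.
#'
#' @param atoms data frame with columns \code{chain}, \code{resno},
#'   \code{resid}, \code{elety}, \code{x}, \code{y}, \code{z} and optionally
#'   \code{subunit}.
#' @return A \code{pb1_structure} object.
#' @export
pb1_structure <- function(atoms) {
  req <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  if (!all(req %in% names(atoms))) {
    stop("atoms must have columns ", paste(req, collapse = ", "))
  }
  if (nrow(atoms) == 0L) stop("structure contains no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("coordinates must be finite")
  }
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key)) stop("duplicate (chain, resno, atom) records")
  if (is.null(atoms$subunit)) atoms$subunit <- NA_integer_
  structure(list(atoms = atoms), class = "pb1_structure")
}

#' @export
print.pb1_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("pb1_structure: %d atoms, %d residue(s), %d chain(s)\n",
              nrow(a), length(unique(paste(a$chain, a$resno))),
              length(unique(a$chain))))
  invisible(x)
}

#' Read / write PDB coordinate files
#'
#' File parsing and writing is delegated to \pkg{bio3d}; alternate locations
#' are reduced to the highest-occupancy conformer (ties to the first), with
#' a message recording the choice.
#'
#' @param path PDB file path.
#' @return \code{read_structure} returns a \code{pb1_structure};
#'   \code{write_structure} returns \code{path} invisibly.
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  a <- pdb$atom
  if (nrow(a) == 0L) stop("no ATOM records in ", path)
  if (any(!is.na(a$alt) & a$alt != "")) {
    # keep the highest-occupancy alternate per (chain, resno, elety)
    key <- paste(a$chain, a$resno, a$elety)
    o <- ifelse(is.na(a$o), 1, a$o)
    keep <- unlist(lapply(split(seq_len(nrow(a)), key), function(i) {
      i[which.max(o[i])]
    }), use.names = FALSE)
    keep <- sort(keep)
    message(sprintf("read_structure: %d alternate-location record(s) dropped",
                    nrow(a) - length(keep)))
    a <- a[keep, , drop = FALSE]
  }
  chain <- ifelse(is.na(a$chain) | a$chain == "", "A", a$chain)
  pb1_structure(data.frame(chain = chain, resno = a$resno, resid = a$resid,
                           elety = a$elety, x = a$x, y = a$y, z = a$z,
                           stringsAsFactors = FALSE))
}

#' @rdname read_structure
#' @param structure a \code{pb1_structure}.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = substr(as.character(a$chain), 1, 1))
  invisible(path)
}

#' Expand an asymmetric unit structure along a helical lattice
#'
#' Applies \code{\link{expand_symmetry}} geometry to every atom; each placed
#' copy becomes its own chain, tagged with the screw-step subunit index.
#' Chain identifiers run A-Z, a-z, 0-9 and switch to numeric tags beyond 62
#' chains (with a message).
#'
#' @param asu a \code{pb1_structure} (the asymmetric unit).
#' @param sym a \code{helical_symmetry}.
#' @param n number of subunits (screw steps) generated (>= 2).
#' @param start_index index of the first subunit.
#' @return A \code{pb1_structure} with \code{subunit} set.
#' @export
expand_structure <- function(asu, sym, n, start_index = 0L) {
  stopifnot(inherits(asu, "pb1_structure"), inherits(sym, "helical_symmetry"))
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("n must be >= 2")
  a <- asu$atoms
  pts <- expand_symmetry(sym, as.matrix(a[, c("x", "y", "z")]),
                         count = n, start_index = start_index)
  natom <- nrow(a)
  ncopy <- nrow(pts) / natom
  pool <- c(LETTERS, letters, as.character(0:9))
  if (ncopy > length(pool)) {
    message("expand_structure: >62 chains, switching to numeric chain tags")
    ids <- paste0("C", seq_len(ncopy))
  } else {
    ids <- pool[seq_len(ncopy)]
  }
  # expand_symmetry emits copies blockwise per (subunit, copy)
  block <- rep(seq_len(ncopy), each = natom)
  out <- data.frame(chain = ids[block],
                    resno = rep(a$resno, times = ncopy),
                    resid = rep(a$resid, times = ncopy),
                    elety = rep(a$elety, times = ncopy),
                    x = pts$x, y = pts$y, z = pts$z,
                    subunit = pts$subunit,
                    stringsAsFactors = FALSE)
  pb1_structure(out)
}

# charged-group heavy atoms per residue class
charge_classes <- function(include_his = FALSE) {
  basic <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ")
  if (include_his) basic$HIS <- c("ND1", "NE2")
  acidic <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  list(basic = basic, acidic = acidic)
}

#' Find inter-residue salt bridges
#'
#' Enumerates all pairs of basic charged-group atoms (Arg NH1/NH2/NE, Lys NZ,
#' optionally His ND1/NE2) and acidic charged-group atoms (Asp OD1/OD2, Glu
#' OE1/OE2) within a distance cutoff, reported once per residue pair at the
#' minimum atom-atom distance, in deterministic order (donor chain/residue,
#' then acceptor).
#'
#' @param structure a \code{pb1_structure}.
#' @param cutoff_A distance cutoff between charged-group heavy atoms
#'   (default 4.0, the conventional salt-bridge criterion).
#' @param include_his include histidine in the basic class (default FALSE;
#'   protonation state is usually unknown).
#' @return Data frame of bridges: donor/acceptor chain, resno, resid, atom,
#'   \code{min_distance_A}, \code{subunit_offset} (acceptor - donor subunit,
#'   NA without expansion tags).
#' @export
find_salt_bridges <- function(structure, cutoff_A = 4.0, include_his = FALSE) {
  stopifnot(inherits(structure, "pb1_structure"))
  a <- structure$atoms
  cls <- charge_classes(include_his)
  pick <- function(defs) {
    sel <- rep(FALSE, nrow(a))
    for (res in names(defs)) sel <- sel | (a$resid == res & a$elety %in% defs[[res]])
    a[sel, , drop = FALSE]
  }
  bas <- pick(cls$basic)
  aci <- pick(cls$acidic)
  known <- c(names(cls$basic), names(cls$acidic),
             "ALA", "VAL", "LEU", "ILE", "PHE", "TRP", "MET", "PRO", "GLY",
             "SER", "THR", "CYS", "TYR", "ASN", "GLN", "HIS")
  unk <- setdiff(unique(a$resid), known)
  if (length(unk)) {
    warning(sprintf("find_salt_bridges: %d unknown residue name(s) skipped: %s",
                    length(unk), paste(head(unk, 5), collapse = ", ")))
  }
  empty <- data.frame(donor_chain = character(0), donor_resno = integer(0),
                      donor_resid = character(0), donor_atom = character(0),
                      acceptor_chain = character(0), acceptor_resno = integer(0),
                      acceptor_resid = character(0), acceptor_atom = character(0),
                      min_distance_A = numeric(0), subunit_offset = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(bas) == 0L || nrow(aci) == 0L) return(empty)

  d2 <- outer(bas$x, aci$x, "-")^2 + outer(bas$y, aci$y, "-")^2 +
    outer(bas$z, aci$z, "-")^2
  hit <- which(d2 <= cutoff_A^2, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty)

  res <- data.frame(
    donor_chain = bas$chain[hit[, 1]], donor_resno = bas$resno[hit[, 1]],
    donor_resid = bas$resid[hit[, 1]], donor_atom = bas$elety[hit[, 1]],
    donor_sub = bas$subunit[hit[, 1]],
    acceptor_chain = aci$chain[hit[, 2]], acceptor_resno = aci$resno[hit[, 2]],
    acceptor_resid = aci$resid[hit[, 2]], acceptor_atom = aci$elety[hit[, 2]],
    acceptor_sub = aci$subunit[hit[, 2]],
    dist = sqrt(d2[hit]), stringsAsFactors = FALSE)

  key <- paste(res$donor_chain, res$donor_resno, res$acceptor_chain,
               res$acceptor_resno)
  best <- unlist(lapply(split(seq_len(nrow(res)), key), function(i) {
    i[which.min(res$dist[i])]
  }), use.names = FALSE)
  res <- res[best, , drop = FALSE]
  res <- res[order(res$donor_chain, res$donor_resno, res$acceptor_chain,
                   res$acceptor_resno), , drop = FALSE]
  out <- data.frame(
    donor_chain = res$donor_chain, donor_resno = res$donor_resno,
    donor_resid = res$donor_resid, donor_atom = res$donor_atom,
    acceptor_chain = res$acceptor_chain, acceptor_resno = res$acceptor_resno,
    acceptor_resid = res$acceptor_resid, acceptor_atom = res$acceptor_atom,
    min_distance_A = res$dist,
    subunit_offset = as.integer(res$acceptor_sub - res$donor_sub),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify inter-subunit contacts as transverse, longitudinal or intra
#'
#' Subunit offset 0 is an intra-unit contact; offset +-1 joins consecutive
#' subunits along the helical rung (transverse). An offset close to a full
#' turn -- axial displacement |offset * rise| within 35 percent of one pitch
#' and |offset| >= round(units per turn) - 1 -- joins neighboring rungs along
#' the helix axis (longitudinal). Everything else is reported as "other".
#'
#' @param bridges bridge table from \code{\link{find_salt_bridges}} with
#'   subunit offsets.
#' @param sym the \code{helical_symmetry} used for expansion.
#' @return The bridge table with a \code{contact_class} column.
#' @export
classify_contacts <- function(bridges, sym) {
  stopifnot(inherits(sym, "helical_symmetry"))
  off <- bridges$subunit_offset
  P <- pitch_of(sym$rise_A, sym$twist_deg)
  U <- units_per_turn(sym$twist_deg)
  axial <- abs(off) * sym$rise_A
  cls <- rep("other", length(off))
  cls[is.na(off)] <- NA_character_
  cls[!is.na(off) & off == 0L] <- "intra"
  cls[!is.na(off) & abs(off) == 1L] <- "transverse"
  lon <- !is.na(off) & abs(off) >= round(U) - 1 & abs(axial - P) <= 0.35 * P
  cls[lon & !(abs(off) <= 1)] <- "longitudinal"
  bridges$contact_class <- cls
  bridges
}

#' Per-residue interface report
#'
#' Aggregates a bridge table per participating residue: partner residues,
#' contact-class counts and minimum distance, sorted by contact count
#' (descending). This is the view in which an arginine finger stands out.
#'
#' @param bridges bridge table, optionally with \code{contact_class}.
#' @return Data frame: \code{chain}, \code{resno}, \code{resid}, \code{role},
#'   \code{n_contacts}, \code{n_transverse}, \code{n_longitudinal},
#'   \code{n_intra}, \code{n_other}, \code{min_distance_A}, \code{partners}.
#' @export
interface_report <- function(bridges) {
  if (nrow(bridges) == 0L) {
    return(data.frame(chain = character(0), resno = integer(0),
                      resid = character(0), role = character(0),
                      n_contacts = integer(0), n_transverse = integer(0),
                      n_longitudinal = integer(0), n_intra = integer(0),
                      n_other = integer(0), min_distance_A = numeric(0),
                      partners = character(0), stringsAsFactors = FALSE))
  }
  if (is.null(bridges$contact_class)) bridges$contact_class <- NA_character_
  sides <- rbind(
    data.frame(chain = bridges$donor_chain, resno = bridges$donor_resno,
               resid = bridges$donor_resid, role = "donor",
               partner = paste0(bridges$acceptor_chain, ":",
                                bridges$acceptor_resid, bridges$acceptor_resno),
               class = bridges$contact_class, dist = bridges$min_distance_A,
               stringsAsFactors = FALSE),
    data.frame(chain = bridges$acceptor_chain, resno = bridges$acceptor_resno,
               resid = bridges$acceptor_resid, role = "acceptor",
               partner = paste0(bridges$donor_chain, ":",
                                bridges$donor_resid, bridges$donor_resno),
               class = bridges$contact_class, dist = bridges$min_distance_A,
               stringsAsFactors = FALSE))
  key <- paste(sides$chain, sides$resno, sides$role)
  rows <- lapply(split(sides, key), function(g) {
    data.frame(chain = g$chain[1], resno = g$resno[1], resid = g$resid[1],
               role = g$role[1], n_contacts = nrow(g),
               n_transverse = sum(g$class == "transverse", na.rm = TRUE),
               n_longitudinal = sum(g$class == "longitudinal", na.rm = TRUE),
               n_intra = sum(g$class == "intra", na.rm = TRUE),
               n_other = sum(g$class == "other", na.rm = TRUE),
               min_distance_A = min(g$dist),
               partners = paste(sort(unique(g$partner)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_contacts, out$chain, out$resno), , drop = FALSE]
  rownames(out) <- NULL
  out
}
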