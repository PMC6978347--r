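test_that("structures validate their atom table", {
  expect_error(pb1_structure(data.frame(chain = "A")), "columns")
  good <- data.frame(chain = "A", resno = 1, resid = "ALA", elety = "CA",
                     x = 0, y = 0, z = 0)
  expect_s3_class(pb1_structure(good), "pb1_structure")
  dup <- rbind(good, good)
  expect_error(pb1_structure(dup), "duplicate")
  bad <- good; bad$x <- NaN
  expect_error(pb1_structure(bad), "finite")
})

test_that("PDB files round-trip through bio3d at format precision", {
  s <- pb1_structure(data.frame(
    chain = "A", resno = c(1, 2), resid = c("ARG", "ASP"),
    elety = c("NH1", "OD1"),
    x = c(1.234, -5.678), y = c(2.5, 0.125), z = c(-0.001, 9.999)))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f)
  r <- read_structure(f)
  expect_equal(nrow(r$atoms), 2L)
  expect_equal(as.matrix(r$atoms[, c("x", "y", "z")]),
               as.matrix(s$atoms[, c("x", "y", "z")]), tolerance = 1e-3,
               ignore_attr = TRUE)

  # alternate locations: keep the highest occupancy
  alt <- c(
    "ATOM      1  CA AALA A   1      11.000  10.000  10.000  0.40 10.00           C",
    "ATOM      2  CA BALA A   1      12.000  10.000  10.000  0.60 10.00           C",
    "END")
  fa <- withr::local_tempfile(fileext = ".pdb")
  writeLines(alt, fa)
  expect_message(ra <- read_structure(fa), "alternate")
  expect_equal(nrow(ra$atoms), 1L)
  expect_equal(ra$atoms$x, 12.0)

  fe <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK empty", "END"), fe)
  expect_error(suppressWarnings(read_structure(fe)))
})

test_that("helical expansion of structures follows the closed-form screw", {
  asu <- pb1_structure(data.frame(chain = "A", resno = 1, resid = "GLY",
                                  elety = "CA", x = 30, y = 0, z = 0))
  sym <- helical_symmetry(5.905, -31.17)
  ex <- expand_structure(asu, sym, n = 2)
  expect_equal(nrow(ex$atoms), 2L)
  d <- sqrt(sum((ex$atoms[2, c("x", "y", "z")] -
                   ex$atoms[1, c("x", "y", "z")])^2))
  closed <- sqrt(5.905^2 + (2 * 30 * sin(abs(-31.17) * pi / 360))^2)
  expect_equal(d, closed, tolerance = 1e-9)

  # copies are rigid: all pairwise intra-subunit distances preserved
  asu2 <- pb1_structure(data.frame(
    chain = "A", resno = 1:3, resid = "GLY", elety = c("N", "CA", "C"),
    x = c(30, 31, 32), y = c(0, 1, -1), z = c(0, 0.5, 1)))
  ex2 <- expand_structure(asu2, sym, n = 4)
  dm <- function(sub) dist(ex2$atoms[ex2$atoms$subunit == sub,
                                     c("x", "y", "z")])
  for (i in 1:3) expect_equal(c(dm(i)), c(dm(0)), tolerance = 1e-9)

  # chain-id exhaustion switches to numeric tags
  expect_message(big <- expand_structure(asu, sym, n = 70), "numeric")
  expect_equal(length(unique(big$atoms$chain)), 70L)
})

test_that("salt-bridge detection matches a brute-force all-pairs scan", {
  # constructed pair at 3.5 A
  s <- pb1_structure(data.frame(
    chain = c("A", "B"), resno = c(21, 69), resid = c("ARG", "ASP"),
    elety = c("NH1", "OD1"), x = c(0, 0), y = c(0, 0), z = c(0, 3.5)))
  br <- find_salt_bridges(s)
  expect_equal(nrow(br), 1L)
  expect_equal(br$min_distance_A, 3.5)
  # beyond the cutoff: empty
  s2 <- s; s2$atoms$z[2] <- 4.5
  expect_equal(nrow(find_salt_bridges(s2)), 0L)

  # toy helical lattice: exact agreement with the independent oracle
  ex <- expand_structure(arg_finger_asu(), u1155_sym(), n = 26)
  expect_lte(nrow(ex$atoms), 5000L)
  br <- find_salt_bridges(ex, cutoff_A = 4.0)
  oracle <- brute_force_bridges(ex, 4.0)
  expect_equal(nrow(br), nrow(oracle))
  expect_equal(paste(br$donor_chain, br$donor_resno, br$acceptor_chain,
                     br$acceptor_resno),
               paste(oracle$donor_chain, oracle$donor_resno,
                     oracle$acceptor_chain, oracle$acceptor_resno))
  expect_equal(br$min_distance_A, oracle$dist, tolerance = 1e-9)

  # unknown residue names are skipped with a warning
  s3 <- pb1_structure(data.frame(
    chain = "A", resno = c(1, 2), resid = c("ARG", "XYZ"),
    elety = c("NH1", "ZZ1"), x = c(0, 1), y = 0, z = c(0, 2)))
  expect_warning(find_salt_bridges(s3), "unknown residue")
})

test_that("bridges are invariant under rigid-body transformation", {
  ex <- expand_structure(arg_finger_asu(), u1155_sym(), n = 15)
  br0 <- find_salt_bridges(ex)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(ex$atoms[, c("x", "y", "z")]) %*% R
  moved <- ex
  moved$atoms$x <- xyz[, 1] + 11
  moved$atoms$y <- xyz[, 2] - 3
  moved$atoms$z <- xyz[, 3] + 250
  br1 <- find_salt_bridges(moved)
  expect_equal(br1$min_distance_A, br0$min_distance_A, tolerance = 1e-9)
  expect_equal(br1$donor_resno, br0$donor_resno)
})

test_that("the interface repeats identically between interior subunits", {
  ex <- expand_structure(arg_finger_asu(), u1155_sym(), n = 20)
  br <- find_salt_bridges(ex)
  br$don_sub <- ex$atoms$subunit[match(br$donor_chain, ex$atoms$chain)]
  per_iface <- split(br, br$don_sub)
  # transverse pattern between (i, i+1) for interior i: same residue pairs,
  # same distances
  sig <- vapply(per_iface, function(g) {
    g <- g[g$subunit_offset == -1, , drop = FALSE]
    paste(paste(g$donor_resno, g$acceptor_resno,
                round(g$min_distance_A, 6)), collapse = ";")
  }, character(1))
  interior <- sig[names(sig) %in% as.character(2:17)]
  expect_equal(length(unique(interior)), 1L)
})

test_that("contacts classify into transverse, longitudinal and intra", {
  sym <- u1155_sym()
  ex <- expand_structure(arg_finger_asu(), sym, n = 26)
  br <- classify_contacts(find_salt_bridges(ex), sym)
  expect_true(all(br$contact_class[abs(br$subunit_offset) == 1] == "transverse"))
  expect_true(all(br$contact_class[br$subunit_offset == 0] == "intra"))
  # the acceptor placed one full turn up gives offset -12 on a U = 11.55
  # lattice: |12 * rise - pitch| = 2.66 A < 0.35 * pitch -> longitudinal
  expect_true(any(br$subunit_offset == -12))
  expect_true(all(br$contact_class[abs(br$subunit_offset) == 12] ==
                    "longitudinal"))
  # hand-computed offset rule
  expect_true(abs(12 * sym$rise_A - pitch_of(sym$rise_A, sym$twist_deg)) <
                0.35 * pitch_of(sym$rise_A, sym$twist_deg))
})

test_that("the per-residue report ranks the arginine finger first", {
  expect_equal(nrow(interface_report(find_salt_bridges(
    pb1_structure(data.frame(chain = "A", resno = 1, resid = "ALA",
                             elety = "CA", x = 0, y = 0, z = 0))))), 0L)
  ex <- expand_structure(arg_finger_asu(), u1155_sym(), n = 12)
  br <- classify_contacts(find_salt_bridges(ex), u1155_sym())
  rep <- interface_report(br)
  donors <- rep[rep$role == "donor", ]
  # the two arginines carry the most contacts
  expect_true(all(donors$resid[1:2] == "ARG"))
  # row count equals the number of distinct (residue, role) participants
  sides <- unique(c(paste(br$donor_chain, br$donor_resno, "donor"),
                    paste(br$acceptor_chain, br$acceptor_resno, "acceptor")))
  expect_equal(nrow(rep), length(sides))
})
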