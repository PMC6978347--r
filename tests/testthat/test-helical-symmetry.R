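test_that("units per turn and pitch reproduce the published lattice values", {
  expect_equal(report_round(units_per_turn(-31.17), 2), 11.55)
  expect_equal(report_round(units_per_turn(-26.48), 2), 13.60)
  expect_equal(report_round(units_per_turn(-25.42), 2), 14.16)
  expect_equal(units_per_turn(180), 2.0)
  expect_equal(units_per_turn(31.17), units_per_turn(-31.17)) # sign-even

  expect_equal(report_round(pitch_of(5.905, -31.17), 1), 68.2)
  expect_equal(pitch_of(1.0, 360), 1.0)
  expect_equal(report_round(pitch_of(9.574, -25.42), 1), 135.6)
  # scale equivariance in rise
  expect_equal(pitch_of(2 * 5.905, -31.17), 2 * pitch_of(5.905, -31.17))
})

test_that("invalid lattice parameters are rejected", {
  expect_error(units_per_turn(0), "non-zero")
  expect_error(pitch_of(-1, 30), "positive")
  expect_error(pitch_of(0, 30), "positive")
  expect_error(helical_symmetry(5, 0), "twist")
  expect_error(helical_symmetry(-5, 30), "rise")
  expect_error(helical_symmetry(5, 30, axial_cyclic = 0), "axial_cyclic")
})

test_that("angle wrapping maps into (-180, 180] with ties at +180", {
  expect_equal(wrap_angle(-180), 180)
  expect_equal(wrap_angle(180), 180)
  expect_equal(wrap_angle(270), -90)
  expect_equal(wrap_angle(-270), 90)
  expect_equal(wrap_angle(334.58), -25.42)
})

test_that("equivalent descriptions regroup asymmetric units correctly", {
  # the two-monomer notation of the p62 L-type lattice
  s <- helical_symmetry(4.787, 77.29, axial_cyclic = 2)
  e <- equivalent_description(s, k = 2, j = 1)
  expect_equal(e$rise_A, 9.574)
  expect_equal(report_round(e$twist_deg, 2), -25.42)
  expect_equal(e$monomers_per_asu, 2L)

  # identity and additive composition
  expect_equal(equivalent_description(s, 1, 0), s)
  s2 <- helical_symmetry(2, 30)
  e2 <- equivalent_description(s2, 3, 0)
  expect_equal(e2$rise_A, 6)
  expect_equal(e2$twist_deg, 90)

  expect_error(equivalent_description(s, 2, 2), "j must")
})

test_that("equivalent descriptions generate identical point sets", {
  set.seed(11)
  canon <- function(df) {
    m <- round(as.matrix(df[, c("x", "y", "z")]), 6)
    m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
  }
  for (cc in c(1L, 2L, 3L)) {
    sym <- helical_symmetry(4.787, 77.29, axial_cyclic = cc)
    asu <- matrix(rnorm(6), 2, 3) * 8
    for (k in 2:4) for (j in seq_len(cc) - 1L) {
      e <- equivalent_description(sym, k, j)
      n_grp <- 8L
      base <- expand_symmetry(sym, asu, count = k * n_grp)
      # composite asymmetric unit: k consecutive subunits, no point-group copies
      s1 <- helical_symmetry(sym$rise_A, sym$twist_deg)
      comp <- expand_symmetry(s1, asu, count = k)
      regrouped <- expand_symmetry(e, as.matrix(comp[, c("x", "y", "z")]),
                                   count = n_grp)
      expect_equal(canon(base), canon(regrouped), tolerance = 1e-6)
    }
  }
})

test_that("rationalize finds the best bounded-denominator approximation", {
  r1 <- rationalize(11.55, 20)
  expect_equal(c(r1$u, r1$t), c(231L, 20L))
  r2 <- rationalize(11.5, 2)
  expect_equal(c(r2$u, r2$t), c(23L, 2L))
  r3 <- rationalize(14.16, 25)
  expect_equal(c(r3$u, r3$t), c(354L, 25L))

  # oracle: exhaustive search over all (u, t) with t <= max_turns
  set.seed(4)
  for (rep in 1:20) {
    U <- runif(1, 1.2, 30)
    mt <- sample(2:30, 1)
    r <- rationalize(U, mt)
    best_err <- Inf
    for (t in 1:mt) for (u in max(1, floor(U * t) - 2):(ceiling(U * t) + 2)) {
      best_err <- min(best_err, abs(u / t - U))
    }
    expect_equal(r$error, best_err, tolerance = 1e-12)
    expect_equal(gcd <- {a <- r$u; b <- r$t; while (b) {tmp <- a %% b; a <- b; b <- tmp}; a}, 1L)
  }
})

test_that("selection rule orders match brute-force enumeration", {
  expect_equal(selection_orders(list(u = 23, t = 2), l = 0, n_max = 30),
               c(-23L, 0L, 23L))
  expect_equal(selection_orders(list(u = 7, t = 3), l = 0, n_max = 0), 0L)
  expect_equal(selection_orders(list(u = 11, t = 1), l = 1, n_max = 12),
               c(-10L, 1L, 12L))

  brute <- function(u, t, l, n_max, m_max = 60) {
    hits <- integer(0)
    for (n in -n_max:n_max) for (m in -m_max:m_max) {
      if (l == t * n + u * m) hits <- c(hits, n)
    }
    sort(unique(hits))
  }
  set.seed(7)
  for (rep in 1:25) {
    u <- sample(2:40, 1); t <- sample(1:5, 1); l <- sample(-10:10, 1)
    expect_equal(selection_orders(list(u = u, t = t), l, 15),
                 brute(u, t, l, 15))
  }
})

test_that("layer-line heights include the meridional and pitch lines", {
  sym <- helical_symmetry(5.905, -31.17)
  ll <- layer_line_heights(sym, n_max = 2, m_max = 1, z_max = 0.2)
  P <- pitch_of(5.905, -31.17)
  # pitch line (n = 1, m = 0)
  expect_true(any(abs(ll$Z - 1 / P) < 1e-9))
  # meridional repeat (n = 0, m = 1)
  expect_true(any(abs(ll$Z - 1 / 5.905) < 1e-9))
  expect_true(all(diff(ll$Z) > 0))
})

test_that("helical expansion is a screw isometry", {
  # full turn returns the azimuth
  sym <- helical_symmetry(3, 90)
  pts <- expand_symmetry(sym, matrix(c(10, 0, 0), 1), count = 5)
  p4 <- pts[pts$subunit == 4, ]
  expect_equal(c(p4$x, p4$y, p4$z), c(10, 0, 12), tolerance = 1e-9)

  # C2 closure: two copies per subunit, 180 degrees apart
  sym2 <- helical_symmetry(4.787, 77.29, axial_cyclic = 2)
  pts2 <- expand_symmetry(sym2, matrix(c(8, 3, 1), 1), count = 4)
  expect_equal(nrow(pts2), 8L)
  for (i in 0:3) {
    pp <- pts2[pts2$subunit == i, ]
    expect_equal(pp$x[1], -pp$x[2], tolerance = 1e-9)
    expect_equal(pp$y[1], -pp$y[2], tolerance = 1e-9)
    expect_equal(pp$z[1], pp$z[2], tolerance = 1e-9)
  }

  # cylindrical radius preserved exactly; consecutive distances constant
  set.seed(2)
  sym3 <- helical_symmetry(5.905, -31.17)
  asu <- matrix(c(40, 5, 2), 1)
  pts3 <- expand_symmetry(sym3, asu, count = 10)
  r <- sqrt(pts3$x^2 + pts3$y^2)
  expect_equal(max(r) - min(r), 0, tolerance = 1e-9)
  d <- sapply(1:9, function(i) {
    a <- pts3[pts3$subunit == i - 1, ]; b <- pts3[pts3$subunit == i, ]
    sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
  })
  expect_equal(max(d) - min(d), 0, tolerance = 1e-9)

  expect_error(expand_symmetry(sym3, matrix(numeric(0), 0, 3), 3),
               "at least one point")
})

test_that("dihedral expansion adds a two-fold related copy", {
  sym <- helical_symmetry(5, 30, dihedral = TRUE)
  pts <- expand_symmetry(sym, matrix(c(10, 2, 1), 1), count = 3)
  expect_equal(nrow(pts), 6L)
  p0 <- pts[pts$subunit == 0, ]
  # two-fold about x: (x, y, z) -> (x, -y, -z)
  expect_equal(p0$x[2], p0$x[1])
  expect_equal(p0$y[2], -p0$y[1])
  expect_equal(p0$z[2], -p0$z[1])
})

test_that("lattice description round-trips to 1e-9 relative tolerance", {
  for (w in c("atnbr1_s", "atnbr1_l", "p62_s", "p62_l")) {
    sym <- pb1_symmetry(w)
    lat <- to_lattice(sym)
    twist_back <- (if (lat$handedness == "left") -1 else 1) *
      360 / lat$units_per_turn
    rise_back <- lat$pitch_A / lat$units_per_turn
    expect_equal(twist_back, sym$twist_deg, tolerance = 1e-9)
    expect_equal(rise_back, sym$rise_A, tolerance = 1e-9)
  }
})

test_that("symmetry JSON serialization round-trips", {
  sym <- helical_symmetry(4.787, 77.29, axial_cyclic = 2, dihedral = TRUE,
                          monomers_per_asu = 2)
  f <- withr::local_tempfile(fileext = ".json")
  write_symmetry_json(sym, f)
  expect_equal(read_symmetry_json(f), sym)
})
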