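test_that("filament models have the expected point bookkeeping", {
  sym <- pb1_symmetry("p62_l")  # C2, one-monomer notation
  mod <- build_filament_model(sym, radius_A = 52, n_subunits = 100)
  expect_equal(nrow(mod$points), 200L)  # 100 screw steps x C2
  r <- sqrt(mod$points$x^2 + mod$points$y^2)
  expect_true(all(abs(r - 52) < 1e-6))
  extent <- diff(range(mod$points$z))
  expect_equal(extent, 99 * sym$rise_A, tolerance = 1e-9)
  expect_error(build_filament_model(sym, 52, n_subunits = 1), "n_subunits")
})

test_that("blob rendering conserves weight and is linear", {
  sym <- helical_symmetry(6, 60)
  one <- build_filament_model(sym, 0, n_subunits = 2, weights = 1)
  # single unit-weight point at the grid center
  one$points <- data.frame(subunit = 0L, copy = 0L, x = 0, y = 0, z = 0,
                           weight = 1)
  img <- render_model(one, c(64, 64), pixel_A = 1, blob_sigma_A = 2)
  expect_equal(sum(img$values) * 1^2, 1, tolerance = 0.01)
  ctr <- floor(64 / 2) + 1
  expect_equal(which(img$values == max(img$values), arr.ind = TRUE)[1, ],
               c(row = ctr, col = ctr))

  # homogeneity: doubling weights doubles every pixel
  two <- one
  two$points$weight <- 2
  img2 <- render_model(two, c(64, 64), 1, 2)
  expect_equal(img2$values, 2 * img$values, tolerance = 1e-12)

  # additivity: two points render as the sum of shifted copies
  pair <- one
  pair$points <- rbind(pair$points, transform(pair$points, x = x + 6))
  imgp <- render_model(pair, c(64, 64), 1, 2)
  shifted <- img$values * 0
  shifted[7:64, ] <- img$values[1:58, ]
  expect_equal(imgp$values, img$values + shifted, tolerance = 1e-6)

  expect_error(render_model(one, c(64, 64), pixel_A = 2, blob_sigma_A = 1),
               "blob_sigma")
})

test_that("3D rendering conserves weight", {
  sym <- helical_symmetry(6, 60)
  mod <- build_filament_model(sym, 5, n_subunits = 3)
  vol <- render_model(mod, c(48, 48, 48), pixel_A = 1, blob_sigma_A = 1.5)
  expect_s3_class(vol, "volume_grid")
  expect_equal(sum(vol$values), sum(mod$points$weight), tolerance = 0.01)
})

test_that("additive noise hits the requested SNR and is reproducible", {
  img <- image_grid(matrix(rnorm(256^2, sd = 2), 256, 256), 1)
  n1 <- add_noise(img, snr = 2, seed = 42)
  n2 <- add_noise(img, snr = 2, seed = 42)
  expect_identical(n1$values, n2$values)
  noise <- n1$values - img$values
  target <- var(as.vector(img$values)) / 2
  expect_equal(var(as.vector(noise)), target, tolerance = 0.05)
  expect_identical(add_noise(img, snr = Inf)$values, img$values)
  expect_error(add_noise(img, snr = -1), "snr")
})

test_that("rendered p62 L-type projections show the lattice's first layer line", {
  # strongest off-equatorial line of a C2 lattice is the lowest allowed
  # (even-order) layer line, at Z = 2/P for the two-monomer notation
  sym <- pb1_symmetry("p62_l_2mer")
  mg <- simulate_micrograph(sym, radius_A = 55, length_A = 1200,
                            pixel_A = 1.04, width_px = 376, snr = 4,
                            seed = 17)
  segs <- suppressMessages(excise_segments(mg$image, mg$axis))
  ps <- power_spectrum(segs)
  pk <- detect_layer_lines(ps, min_snr = 5, z_exclusion_px = 2.5)
  strongest <- pk[which.max(pk$amplitude), ]
  P <- pitch_of(sym$rise_A, sym$twist_deg)
  ll <- layer_line_heights(sym, n_max = 2, m_max = 0, z_max = 0.05)
  z_first <- min(ll$Z[ll$Z > 1e-9])
  expect_equal(z_first, 2 / P, tolerance = 1e-9)
  expect_lt(abs(strongest$z_height - z_first), ps$fourier_px)
})

test_that("tomogram simulation matches its ground truth", {
  # empty spec
  sp0 <- tomogram_spec(n_filaments = 0, shape = c(24L, 24L, 24L))
  sim0 <- simulate_tomogram(sp0)
  expect_equal(nrow(sim0$ground_truth), 0L)
  expect_true(all(sim0$volume$values == 0))

  # single straight tube: cylinder-volume oracle
  sp1 <- tomogram_spec(n_filaments = 1, diameter_sd_nm = 0,
                       length_meanlog = log(30), length_sdlog = 1e-9,
                       bend_sd_deg = 0, snr = Inf, seed = 3)
  sim1 <- simulate_tomogram(sp1)
  expect_equal(sim1$ground_truth$diameter_nm, 15)
  expect_equal(sim1$ground_truth$length_nm, 30, tolerance = 1e-6)
  fg <- sum(sim1$volume$values > 0.5)
  expect_equal(fg, pi * 7.5^2 * 30, tolerance = 0.1)

  # reproducibility under a fixed seed
  spA <- tomogram_spec(n_filaments = 5, seed = 9)
  expect_identical(simulate_tomogram(spA)$ground_truth,
                   simulate_tomogram(spA)$ground_truth)
  expect_error(tomogram_spec(diameter_mean_nm = 1, voxel_nm = 1), ">= 2 voxels")
})

test_that("isotherm simulation follows the one-site model", {
  p0 <- one_site_params(8.9e-9, dh_cal_mol = 0, n_sites = 1,
                        cell_conc_M = 10e-6, syringe_conc_M = 50e-6)
  iso0 <- simulate_isotherm(p0)
  expect_true(all(iso0$heats_ucal == 0))

  p <- one_site_params(8.9e-9, dh_cal_mol = -8000, n_sites = 1,
                       cell_conc_M = 10e-6, syringe_conc_M = 50e-6)
  iso <- simulate_isotherm(p, noise_sd_ucal = 0)
  expect_equal(iso$heats_ucal, predict_heats(p, iso$injection_volumes_L))

  # tight binder: sharply sigmoidal with its transition near molar ratio 1
  ratio <- molar_ratio(iso)
  h <- abs(iso$heats_ucal)
  i_drop <- which(h < max(h) / 2)[1]
  expect_gt(ratio[i_drop], 0.85)
  expect_lt(ratio[i_drop], 1.15)
  # early injections near-constant (all ligand bound), late near zero
  expect_gt(h[1], 10 * h[length(h)])

  n1 <- simulate_isotherm(p, noise_sd_ucal = 0.5, seed = 5)
  n2 <- simulate_isotherm(p, noise_sd_ucal = 0.5, seed = 5)
  expect_identical(n1$heats_ucal, n2$heats_ucal)
})

test_that("melt curves have the stated schedule and a clean inflection", {
  m <- simulate_melt(50)
  expect_length(m$temperature_C, 151L)
  expect_equal(range(m$temperature_C), c(15, 90))

  # noiseless flat-baseline curve: numerical inflection exactly at Tm
  d <- diff(m$fluorescence) / diff(m$temperature_C)
  t_mid <- (m$temperature_C[-1] + m$temperature_C[-151]) / 2
  expect_equal(t_mid[which.max(d)], 50, tolerance = 0.5)

  m1 <- simulate_melt(62, noise_sd = 0.02, seed = 8)
  m2 <- simulate_melt(62, noise_sd = 0.02, seed = 8)
  expect_identical(m1$fluorescence, m2$fluorescence)
  expect_error(simulate_melt(100), "t_range")
})

test_that("isotherm and melt CSV round-trips preserve data and metadata", {
  p <- one_site_params(26.8e-9, -8000, 1, 10e-6, 100e-6)
  iso <- simulate_isotherm(p, noise_sd_ucal = 0.2, seed = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_isotherm_csv(iso, f)
  r <- read_isotherm_csv(f)
  expect_equal(r$heats_ucal, iso$heats_ucal)
  expect_equal(r$cell_conc_M, iso$cell_conc_M)
  expect_equal(r$v0_L, iso$v0_L)

  m <- simulate_melt(55, noise_sd = 0.01, seed = 2)
  fm <- withr::local_tempfile(fileext = ".csv")
  write_melt_csv(m, fm)
  rm <- read_melt_csv(fm)
  expect_equal(rm$fluorescence, m$fluorescence)
})
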