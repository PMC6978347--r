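#' Built-in helical parameter sets
#'
#' The published helical-reconstruction parameters of the four PB1-domain
#' filament structures (plant NBR1 and human p62, each in its L-type and
#' S-type lattice), as \code{helical_symmetry} objects. The p62 L-type is
#' available in both its one-monomer (4.787 A / 77.29 deg, C2) and
#' two-monomer (9.574 A / -25.42 deg) notations.
#'
#' @param which one of "atnbr1_s", "atnbr1_l", "p62_s", "p62_l",
#'   "p62_l_2mer".
#' @return A \code{helical_symmetry}.
#' @export
pb1_symmetry <- function(which = c("atnbr1_s", "atnbr1_l", "p62_s", "p62_l",
                                   "p62_l_2mer")) {
  which <- match.arg(which)
  switch(which,
    atnbr1_s = helical_symmetry(5.905, -31.17, axial_cyclic = 1L),
    atnbr1_l = helical_symmetry(6.721, -31.44, axial_cyclic = 2L),
    p62_s = helical_symmetry(9.78, -26.48, axial_cyclic = 1L),
    p62_l = helical_symmetry(4.787, 77.29, axial_cyclic = 2L),
    p62_l_2mer = equivalent_description(
      helical_symmetry(4.787, 77.29, axial_cyclic = 2L), k = 2L, j = 1L))
}

#' Run a canned analysis recipe
#'
#' Reproduces one of the package's desk-scale validation experiments end to
#' end and returns a machine-readable report. Recipes:
#' \describe{
#'   \item{table1_checks}{helical-parameter arithmetic against the published
#'     values at printed precision.}
#'   \item{symmetry_recovery}{render noisy synthetic filaments, excise
#'     segments, average power spectra, detect layer lines, index, and
#'     grid-search; compare with the generating symmetry.}
#'   \item{morphometry_recovery}{simulate a filament tomogram and recover
#'     mean width/length against ground truth.}
#'   \item{itc_recovery}{recover generating binding constants from synthetic
#'     one-site isotherms, noiseless and noisy, plus a melt-curve Tm check.}
#' }
#'
#' @param name recipe name.
#' @param seed integer seed for every stochastic step.
#' @param out optional path; the report is written there as JSON.
#' @return The report, a named list with a \code{pass} flag per check.
#' @export
run_recipe <- function(name = c("table1_checks", "symmetry_recovery",
                                "morphometry_recovery", "itc_recovery"),
                       seed = 1L, out = NULL) {
  name <- tryCatch(match.arg(name), error = function(e)
    stop("unknown recipe; available: table1_checks, symmetry_recovery, ",
         "morphometry_recovery, itc_recovery"))
  seed <- as.integer(seed)
  report <- switch(name,
    table1_checks = recipe_table1(),
    symmetry_recovery = recipe_symmetry(seed),
    morphometry_recovery = recipe_morphometry(seed),
    itc_recovery = recipe_itc(seed))
  report$recipe <- name
  report$seed <- seed
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  report
}

recipe_table1 <- function() {
  checks <- list(
    atnbr1_s_units_per_turn = list(
      value = report_round(units_per_turn(-31.17), 2), printed = 11.55),
    atnbr1_s_pitch_A = list(
      value = report_round(pitch_of(5.905, -31.17), 1), printed = 68.2),
    p62_s_units_per_turn = list(
      value = report_round(units_per_turn(-26.48), 2), printed = 13.60),
    p62_l_units_per_turn = list(
      value = report_round(units_per_turn(-25.42), 2), printed = 14.16))
  two <- pb1_symmetry("p62_l_2mer")
  checks$p62_l_2mer_rise_A <- list(
    value = report_round(two$rise_A, 3), printed = 9.574)
  checks$p62_l_2mer_twist_deg <- list(
    value = report_round(two$twist_deg, 2), printed = -25.42)
  for (k in names(checks)) {
    checks[[k]]$pass <- checks[[k]]$value == checks[[k]]$printed
  }
  list(checks = checks, pass = all(vapply(checks, `[[`, logical(1), "pass")))
}

# one symmetry-recovery experiment: micrograph -> segments -> spectrum ->
# peaks -> indexing -> grid search
recover_symmetry <- function(sym, radius_A, pixel_A, pitch_bounds,
                             rise_bounds, n_starts, snr = 2, seed = 1L,
                             length_A = 3000, min_snr = 5,
                             grid_refine = TRUE) {
  mg <- simulate_micrograph(sym, radius_A = radius_A, length_A = length_A,
                            pixel_A = pixel_A,
                            width_px = 2L * (as.integer(round(350 / pixel_A)) %/% 2L) + 40L,
                            blob_sigma_A = 2.5, snr = snr, seed = seed)
  segs <- excise_segments(mg$image, mg$axis, box_A = 350, step_A = 60)
  ps <- power_spectrum(segs)
  # tapered windows leak the (dominant) equator into the first couple of
  # rows; exclude a slightly wider band than the default
  peaks <- detect_layer_lines(ps, min_snr = min_snr, z_exclusion_px = 2.5)
  cand <- index_candidates(peaks,
                           pitch_bounds = pitch_bounds,
                           rise_bounds = rise_bounds,
                           pitch_step = 0.5, rise_step = 0.05,
                           n_starts = n_starts, radius_A = radius_A,
                           tol_A_inv = Inf)
  best <- cand[1, ]

  gs <- NULL
  if (grid_refine) {
    upt0 <- best$units_per_turn
    P0 <- best$pitch_A
    c_ord <- sym$axial_cyclic
    simulator <- function(P, U) {
      s <- helical_symmetry(P / U, -360 / U, axial_cyclic = c_ord,
                            dihedral = sym$dihedral)
      m <- build_filament_model(s, radius_A,
                                n_subunits = as.integer(ceiling(400 / s$rise_A)))
      img <- suppressWarnings(render_model(m, dim(segs[[1]]$values),
                                           pixel_A, 2.5))
      power_spectrum(img)
    }
    gs <- grid_search_symmetry(ps,
                               pitch_grid = seq(P0 - 2, P0 + 2, by = 0.5),
                               upt_grid = seq(upt0 - 0.2, upt0 + 0.2,
                                              by = 0.05),
                               simulator = simulator)
  }
  list(n_segments = length(segs), n_peaks = nrow(peaks), peaks = peaks,
       candidates = cand, indexed = best, grid = gs)
}

recipe_symmetry <- function(seed = 1L) {
  sym_a <- pb1_symmetry("atnbr1_s")
  rec_a <- recover_symmetry(sym_a, radius_A = 40, pixel_A = 1.386,
                            pitch_bounds = c(50, 90),
                            rise_bounds = c(5, 7),
                            n_starts = 1:2, snr = 2, seed = seed)
  true_a <- to_lattice(sym_a)

  sym_p <- pb1_symmetry("p62_l_2mer")
  rec_p <- recover_symmetry(sym_p, radius_A = 55, pixel_A = 1.04,
                            pitch_bounds = c(110, 160),
                            rise_bounds = c(8.5, 10.5),
                            n_starts = 1:3, snr = 2, seed = seed + 1L)
  true_p <- to_lattice(sym_p)

  mk <- function(rec, truth) {
    dU <- abs(rec$indexed$units_per_turn - truth$units_per_turn)
    dP <- abs(rec$indexed$pitch_A - truth$pitch_A)
    gpass <- !is.null(rec$grid) &&
      abs(rec$grid$pitch_A - truth$pitch_A) <= 0.5 + 1e-9 &&
      abs(rec$grid$units_per_turn - truth$units_per_turn) <= 0.05 + 1e-9
    list(recovered_pitch_A = rec$indexed$pitch_A,
         recovered_units_per_turn = rec$indexed$units_per_turn,
         recovered_n_starts = rec$indexed$n_starts,
         true_pitch_A = truth$pitch_A,
         true_units_per_turn = truth$units_per_turn,
         n_peaks = rec$n_peaks, n_segments = rec$n_segments,
         grid_pitch_A = if (!is.null(rec$grid)) rec$grid$pitch_A else NA,
         grid_units_per_turn = if (!is.null(rec$grid)) rec$grid$units_per_turn else NA,
         pass = dU <= 0.1 && dP <= 1 && gpass)
  }
  ca <- mk(rec_a, true_a)
  cp <- mk(rec_p, true_p)
  list(atnbr1_s = ca, p62_l = cp, pass = ca$pass && cp$pass)
}

recipe_morphometry <- function(seed = 1L, n_replicates = 3L) {
  reps <- lapply(seq_len(n_replicates), function(k) {
    spec <- tomogram_spec(seed = seed + k - 1L)
    sim <- simulate_tomogram(spec)
    m <- tomogram_morphometry(sim$volume, min_voxels = 200L)
    list(mean_width_nm = m$mean_width_nm,
         mean_length_nm = m$mean_length_nm,
         true_mean_width_nm = mean(sim$ground_truth$diameter_nm),
         true_mean_length_nm = mean(sim$ground_truth$length_nm),
         n_traces = m$n_traces,
         n_true = nrow(sim$ground_truth))
  })
  w <- mean(vapply(reps, `[[`, numeric(1), "mean_width_nm"))
  l <- mean(vapply(reps, `[[`, numeric(1), "mean_length_nm"))
  tw <- mean(vapply(reps, `[[`, numeric(1), "true_mean_width_nm"))
  tl <- mean(vapply(reps, `[[`, numeric(1), "true_mean_length_nm"))
  list(replicates = reps,
       mean_width_nm = w, true_mean_width_nm = tw,
       mean_length_nm = l, true_mean_length_nm = tl,
       width_rel_err = abs(w - tw) / tw,
       length_rel_err = abs(l - tl) / tl,
       pass = abs(w - tw) / tw <= 0.10 && abs(l - tl) / tl <= 0.15)
}

recipe_itc <- function(seed = 1L) {
  kds_nM <- c(8.9, 12.6, 26.8, 105)
  noiseless <- lapply(kds_nM, function(kd) {
    p <- one_site_params(kd * 1e-9, dh_cal_mol = -8000, n_sites = 1,
                         cell_conc_M = 10e-6, syringe_conc_M = 100e-6)
    iso <- simulate_isotherm(p)
    fit <- fit_one_site(iso)
    list(kd_true_nM = kd, kd_fit_nM = fit$kd_M * 1e9,
         rel_err = abs(fit$kd_M * 1e9 - kd) / kd,
         pass = abs(fit$kd_M * 1e9 - kd) / kd <= 0.01)
  })
  names(noiseless) <- paste0("kd_", gsub("\\.", "p", kds_nM), "_nM")

  # noisy recovery: sigma = 0.5% of the first-injection heat scale, 3 seeds
  p <- one_site_params(26.8e-9, dh_cal_mol = -8000, n_sites = 1,
                       cell_conc_M = 10e-6, syringe_conc_M = 100e-6)
  scale_ucal <- abs(predict_heats(p, rep(10e-6, 28))[1])
  noisy <- lapply(1:3, function(k) {
    iso <- simulate_isotherm(p, noise_sd_ucal = 0.005 * scale_ucal,
                             seed = seed + k - 1L)
    fit <- fit_one_site(iso)
    list(kd_fit_nM = fit$kd_M * 1e9, kd_se_nM = fit$kd_se_M * 1e9,
         pass = abs(fit$kd_M - 26.8e-9) <= 3 * fit$kd_se_M)
  })

  mc <- lapply(1:3, function(k)
    simulate_melt(50, noise_sd = 0.01, seed = seed + 10L + k,
                  baseline_pre = c(0.05, 0.002),
                  baseline_post = c(0.05, 0.002)))
  mf <- fit_melt(mc)

  list(noiseless = noiseless, noisy = noisy,
       melt_tm_C = mf$tm_mean_C, melt_tm_sd_C = mf$tm_sd_C,
       pass = all(vapply(noiseless, `[[`, logical(1), "pass")) &&
         all(vapply(noisy, `[[`, logical(1), "pass")) &&
         abs(mf$tm_mean_C - 50) < 0.5)
}
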