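#' One-site binding parameters
#'
#' @param kd_M dissociation constant, mol/L (> 0).
#' @param dh_cal_mol binding enthalpy per mole of injectant, cal/mol.
#' @param n_sites stoichiometry (sites per cell molecule, > 0).
#' @param cell_conc_M initial cell (macromolecule) concentration, mol/L.
#' @param syringe_conc_M syringe (ligand) concentration, mol/L.
#' @param v0_L calorimeter cell volume, liters (default 1.4e-3, a standard
#'   perfusion cell).
#' @return A \code{one_site_params} object.
#' @export
one_site_params <- function(kd_M, dh_cal_mol, n_sites = 1,
                            cell_conc_M, syringe_conc_M, v0_L = 1.4e-3) {
  if (kd_M <= 0) stop("kd_M must be > 0")
  if (n_sites <= 0) stop("n_sites must be > 0")
  if (cell_conc_M <= 0 || syringe_conc_M <= 0) stop("concentrations must be > 0")
  if (v0_L <= 0) stop("v0_L must be > 0")
  structure(list(kd_M = kd_M, dh_cal_mol = dh_cal_mol, n_sites = n_sites,
                 cell_conc_M = cell_conc_M, syringe_conc_M = syringe_conc_M,
                 v0_L = v0_L),
            class = "one_site_params")
}

#' Predict per-injection heats of a one-site titration
#'
#' Standard single-site isotherm with perfusion-cell dilution bookkeeping
#' (displaced volume leaves the cell): after a cumulative injected volume dV,
#' total concentrations are Mt = M0 (1 - dV/2V0)/(1 + dV/2V0) and
#' Xt = X0 (dV/V0)/(1 + dV/2V0). The bound fraction follows the quadratic
#' root Theta = (S - sqrt(S^2 - 4 Xt/(N Mt)))/2 with
#' S = 1 + Xt/(N Mt) + Kd/(N Mt); cumulative heat Q = N Theta Mt dH V0 and
#' the per-injection heat is the difference plus the displaced-volume
#' correction (dVi/V0)(Qi + Qi-1)/2.
#'
#' @param params a \code{one_site_params}.
#' @param injection_volumes_L per-injection volumes, liters.
#' @return Numeric vector of per-injection heats, microcalories.
#' @export
predict_heats <- function(params, injection_volumes_L) {
  stopifnot(inherits(params, "one_site_params"))
  dV <- injection_volumes_L
  if (any(dV <= 0)) stop("injection volumes must be > 0")
  V0 <- params$v0_L
  cum <- cumsum(dV)
  Mt <- params$cell_conc_M * (1 - cum / (2 * V0)) / (1 + cum / (2 * V0))
  Xt <- params$syringe_conc_M * (cum / V0) / (1 + cum / (2 * V0))
  N <- params$n_sites
  r <- Xt / (N * Mt)
  S <- 1 + r + params$kd_M / (N * Mt)
  disc <- S^2 - 4 * r
  if (any(disc < 0)) {
    if (any(disc < -1e-8)) warning("negative discriminant clamped to 0")
    disc <- pmax(disc, 0)
  }
  theta <- (S - sqrt(disc)) / 2
  Q <- N * theta * Mt * params$dh_cal_mol * V0     # cal
  Qprev <- c(0, Q[-length(Q)])
  dq <- Q - Qprev + (dV / V0) * (Q + Qprev) / 2
  dq * 1e6                                          # microcal
}

#' Simulate a noisy ITC injection series
#'
#' @param params a \code{one_site_params}.
#' @param injection_volumes_L per-injection volumes, liters (default
#'   28 injections of 10 microliters).
#' @param noise_sd_ucal Gaussian noise SD on each heat, microcalories.
#' @param seed RNG seed.
#' @return An \code{isotherm}: injection volumes, heats (microcal), and the
#'   cell/syringe concentrations carried along for fitting.
#' @export
simulate_isotherm <- function(params, injection_volumes_L = rep(10e-6, 28),
                              noise_sd_ucal = 0, seed = NULL) {
  q <- predict_heats(params, injection_volumes_L)
  if (noise_sd_ucal > 0) {
    q <- q + local_seed(seed, rnorm(length(q), sd = noise_sd_ucal))
  }
  structure(list(injection_volumes_L = injection_volumes_L,
                 heats_ucal = q,
                 cell_conc_M = params$cell_conc_M,
                 syringe_conc_M = params$syringe_conc_M,
                 v0_L = params$v0_L),
            class = "isotherm")
}

#' @export
print.isotherm <- function(x, ...) {
  cat(sprintf("isotherm: %d injections, cell %.3g M, syringe %.3g M\n",
              length(x$heats_ucal), x$cell_conc_M, x$syringe_conc_M))
  invisible(x)
}

#' Molar ratio (ligand over cell molecule) after each injection
#' @param isotherm an \code{isotherm}.
#' @return Numeric vector.
#' @export
molar_ratio <- function(isotherm) {
  cum <- cumsum(isotherm$injection_volumes_L)
  V0 <- isotherm$v0_L
  Xt <- isotherm$syringe_conc_M * (cum / V0) / (1 + cum / (2 * V0))
  Mt <- isotherm$cell_conc_M * (1 - cum / (2 * V0)) / (1 + cum / (2 * V0))
  Xt / Mt
}

#' Correct an isotherm by the basal heat after saturation
#'
#' Subtracts the mean of the last \code{k_last} injection heats (the residual
#' heat of injection once binding is saturated) from every injection.
#' Idempotent.
#'
#' @param isotherm an \code{isotherm}.
#' @param k_last number of trailing injections averaged (default 3).
#' @return The corrected \code{isotherm} (with attribute \code{basal_ucal}).
#' @export
correct_baseline <- function(isotherm, k_last = 3L) {
  stopifnot(inherits(isotherm, "isotherm"))
  n <- length(isotherm$heats_ucal)
  if (k_last > n) stop("k_last exceeds the number of injections")
  basal <- mean(tail(isotherm$heats_ucal, k_last))
  isotherm$heats_ucal <- isotherm$heats_ucal - basal
  attr(isotherm, "basal_ucal") <- basal
  isotherm
}

#' Fit the one-site binding model to an isotherm
#'
#' Nonlinear least squares (Levenberg-Marquardt) on the per-injection heats,
#' estimating Kd, dH and N. Kd is fitted on the log scale; the initial guess
#' is taken from the curve geometry (N from the molar ratio at half-height,
#' dH from the first-injection amplitude) with a small multistart over the
#' binding strength. A warning is issued when the Wiseman c-value
#' (N * cell / Kd) leaves the identifiable range [1, 1e4] or when the fit is
#' uninformative.
#'
#' @param isotherm an \code{isotherm}.
#' @param start optional named list (kd_M, dh_cal_mol, n_sites) overriding
#'   the automatic initial guess.
#' @return An \code{itc_fit}: estimated \code{one_site_params}, standard
#'   errors, c-value, residuals and the underlying \code{nls} object.
#' @export
fit_one_site <- function(isotherm, start = NULL) {
  stopifnot(inherits(isotherm, "isotherm"))
  q <- isotherm$heats_ucal
  dV <- isotherm$injection_volumes_L
  n_inj <- length(q)
  if (n_inj < 6L) stop("at least 6 injections are required")

  model_fun <- function(log_kd, dh, n_sites) {
    p <- one_site_params(exp(log_kd), dh, n_sites,
                         isotherm$cell_conc_M, isotherm$syringe_conc_M,
                         isotherm$v0_L)
    predict_heats(p, dV)
  }

  # geometric initial guesses
  ratio <- molar_ratio(isotherm)
  amp0 <- q[1]
  moles1 <- dV[1] * isotherm$syringe_conc_M
  dh_init <- if (!is.null(start$dh_cal_mol)) start$dh_cal_mol else
    amp0 * 1e-6 / moles1
  half <- which(abs(q) <= abs(amp0) / 2)
  n_init <- if (!is.null(start$n_sites)) start$n_sites else {
    h <- if (length(half)) ratio[half[1]] else ratio[ceiling(n_inj / 2)]
    max(0.2, min(5, h))
  }
  kd_inits <- if (!is.null(start$kd_M)) start$kd_M else
    isotherm$cell_conc_M * n_init / c(10, 100, 1000)

  best <- NULL
  for (kd0 in kd_inits) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        q ~ model_fun(log_kd, dh, n_sites),
        start = list(log_kd = log(kd0), dh = dh_init, n_sites = n_init),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    # uninformative data: no start converges; fall back to a direct search
    # so the guard below can report the identifiability problem
    ssr <- function(par) {
      pred <- tryCatch(model_fun(par[1], par[2], exp(par[3])),
                       error = function(e) rep(Inf, n_inj))
      sum((q - pred)^2)
    }
    op <- stats::optim(c(log(kd_inits[1]), dh_init, log(n_init)), ssr)
    cf <- c(log_kd = op$par[1], dh = op$par[2], n_sites = exp(op$par[3]))
    kd <- exp(cf[["log_kd"]])
    se <- c(log_kd = NA_real_, dh = NA_real_, n_sites = NA_real_)
    kd_se <- NA_real_
    best <- list(fit = NULL, rss = op$value)
    fit <- NULL
  } else {
    fit <- best$fit
    cf <- coef(fit)
    kd <- exp(cf[["log_kd"]])
    se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
      rep(NA_real_, 3))
    names(se) <- names(cf)
    kd_se <- kd * se[["log_kd"]]  # delta method
  }

  cval <- cf[["n_sites"]] * isotherm$cell_conc_M / kd
  tot_var <- var(q) * (n_inj - 1)
  r2 <- 1 - best$rss / tot_var
  informative <- is.finite(r2) && r2 > 0.5 &&
    is.finite(se[["log_kd"]]) && se[["log_kd"]] < 2
  if (!informative) {
    warning("fit_one_site: binding parameters are not identifiable from these data")
  } else if (cval < 1 || cval > 1e4) {
    warning(sprintf("fit_one_site: c-value %.3g outside [1, 1e4]; Kd weakly identifiable",
                    cval))
  }

  structure(list(
    params = one_site_params(kd, cf[["dh"]], cf[["n_sites"]],
                             isotherm$cell_conc_M, isotherm$syringe_conc_M,
                             isotherm$v0_L),
    kd_M = kd, kd_se_M = kd_se,
    dh_cal_mol = cf[["dh"]], dh_se = se[["dh"]],
    n_sites = cf[["n_sites"]], n_se = se[["n_sites"]],
    c_value = cval, r_squared = r2, informative = informative,
    isotherm = isotherm, nls = fit), class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat("One-site ITC fit\n")
  cat(sprintf("  Kd = %.4g M (SE %.2g)  [%.4g nM]\n", x$kd_M, x$kd_se_M,
              x$kd_M * 1e9))
  cat(sprintf("  dH = %.4g cal/mol (SE %.2g)\n", x$dh_cal_mol, x$dh_se))
  cat(sprintf("  N  = %.4g (SE %.2g), c-value %.3g\n", x$n_sites, x$n_se,
              x$c_value))
  invisible(x)
}

#' @export
coef.itc_fit <- function(object, ...) {
  c(kd_M = object$kd_M, dh_cal_mol = object$dh_cal_mol,
    n_sites = object$n_sites)
}

#' @export
summary.itc_fit <- function(object, ...) {
  out <- data.frame(
    estimate = c(object$kd_M, object$dh_cal_mol, object$n_sites),
    se = c(object$kd_se_M, object$dh_se, object$n_se),
    row.names = c("kd_M", "dh_cal_mol", "n_sites"))
  cat(sprintf("One-site ITC fit (c = %.3g, R^2 = %.4f)\n", object$c_value,
              object$r_squared))
  print(out)
  invisible(out)
}

#' @export
predict.itc_fit <- function(object, ...) {
  predict_heats(object$params, object$isotherm$injection_volumes_L)
}

#' @export
residuals.itc_fit <- function(object, ...) {
  object$isotherm$heats_ucal - predict(object)
}

#' @export
plot.itc_fit <- function(x, ...) {
  r <- molar_ratio(x$isotherm)
  graphics::plot(r, x$isotherm$heats_ucal, xlab = "molar ratio",
                 ylab = "heat (ucal)", ...)
  graphics::lines(r, predict(x))
  invisible(x)
}

#' Read / write isotherm CSV
#'
#' A small CSV dialect with a '#'-prefixed metadata block (cell and syringe
#' concentrations, cell volume) followed by columns injection_volume_L,
#' heat_ucal.
#'
#' @param isotherm an \code{isotherm}.
#' @param path file path.
#' @return \code{read_isotherm_csv} returns an \code{isotherm}.
#' @export
write_isotherm_csv <- function(isotherm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# cell_conc_M %.12g", isotherm$cell_conc_M),
               sprintf("# syringe_conc_M %.12g", isotherm$syringe_conc_M),
               sprintf("# v0_L %.12g", isotherm$v0_L)), con)
  write.csv(data.frame(injection_volume_L = isotherm$injection_volumes_L,
                       heat_ucal = isotherm$heats_ucal),
            con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_isotherm_csv
#' @export
read_isotherm_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    parts <- strsplit(sub("^#\\s*", "", ln), "\\s+")[[1]]
    meta[[parts[1]]] <- as.numeric(parts[2])
  }
  df <- read.csv(textConnection(lines[!grepl("^#", lines)]))
  structure(list(injection_volumes_L = df$injection_volume_L,
                 heats_ucal = df$heat_ucal,
                 cell_conc_M = meta$cell_conc_M,
                 syringe_conc_M = meta$syringe_conc_M,
                 v0_L = meta$v0_L),
            class = "isotherm")
}
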