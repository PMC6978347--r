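#' Simulate a thermal-unfolding fluorescence curve
#'
#' Two-state melt read out by dye fluorescence: a logistic transition between
#' linear folded and unfolded baselines, plus Gaussian noise. The default
#' temperature schedule (15 to 90 degrees C in 0.5 degree steps) gives 151
#' samples.
#'
#' @param tm_C melting temperature (inflection), within the scanned range.
#' @param steepness_C transition width parameter (degrees C; default 1.5).
#' @param baseline_pre c(intercept, slope) of the folded baseline.
#' @param baseline_post c(intercept, slope) of the unfolded baseline.
#' @param amplitude fluorescence jump across the transition.
#' @param noise_sd Gaussian noise SD (fluorescence units).
#' @param seed RNG seed.
#' @param t_range scanned range, degrees C.
#' @param step_C temperature step, degrees C.
#' @return A \code{melt_curve}: \code{temperature_C}, \code{fluorescence}.
#' @export
simulate_melt <- function(tm_C, steepness_C = 1.5,
                          baseline_pre = c(0, 0), baseline_post = c(0, 0),
                          amplitude = 1, noise_sd = 0, seed = NULL,
                          t_range = c(15, 90), step_C = 0.5) {
  if (tm_C < t_range[1] || tm_C > t_range[2]) {
    stop("tm_C must lie within t_range")
  }
  temp <- seq(t_range[1], t_range[2], by = step_C)
  theta <- 1 / (1 + exp(-(temp - tm_C) / steepness_C))
  f <- (baseline_pre[1] + baseline_pre[2] * temp) * (1 - theta) +
    (baseline_post[1] + baseline_post[2] * temp + amplitude) * theta
  if (noise_sd > 0) {
    f <- f + local_seed(seed, rnorm(length(f), sd = noise_sd))
  }
  structure(list(temperature_C = temp, fluorescence = f),
            class = "melt_curve")
}

#' @export
print.melt_curve <- function(x, ...) {
  cat(sprintf("melt_curve: %d points, %.4g to %.4g C\n",
              length(x$temperature_C), min(x$temperature_C),
              max(x$temperature_C)))
  invisible(x)
}

#' Fit melting temperatures to replicate melt curves
#'
#' Per replicate: fit a linear pre-transition baseline (robust region below
#' the transition), subtract it, normalize to maximum fluorescence, and fit a
#' four-parameter logistic; the apparent Tm is the inflection point. The
#' replicate mean and SD of Tm are reported.
#'
#' @param curves a \code{melt_curve} or list of replicate \code{melt_curve}s.
#' @return A \code{melt_fit}: per-replicate table (\code{tm_C},
#'   \code{steepness_C}, \code{rss}), \code{tm_mean_C}, \code{tm_sd_C}.
#' @export
fit_melt <- function(curves) {
  if (inherits(curves, "melt_curve")) curves <- list(curves)
  fits <- lapply(seq_along(curves), function(i) {
    cv <- curves[[i]]
    tm1 <- fit_melt_one(cv)
    cbind(replicate = i, tm1)
  })
  tab <- do.call(rbind, fits)
  structure(list(replicates = tab,
                 tm_mean_C = mean(tab$tm_C),
                 tm_sd_C = if (nrow(tab) > 1) sd(tab$tm_C) else 0),
            class = "melt_fit")
}

fit_melt_one <- function(curve) {
  temp <- curve$temperature_C
  f <- curve$fluorescence
  if (length(temp) < 20L) stop("at least 20 temperature points are required")
  if (any(diff(temp) <= 0)) stop("temperatures must be strictly increasing")

  rngf <- diff(range(f))
  if (rngf <= 0 || rngf < 6 * stats::mad(diff(f)) / sqrt(2)) {
    stop("no transition detected in melt curve")
  }
  # rough transition midpoint from the smoothed derivative
  sm <- stats::filter(f, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- f[is.na(sm)]
  dfdt <- diff(sm) / diff(temp)
  i_mid <- which.max(abs(dfdt))
  t_mid <- temp[i_mid]
  width <- max(2, diff(range(temp)) / 25)

  pre <- temp < t_mid - 3 * width
  if (sum(pre) < 5L) pre <- seq_along(temp) <= max(5L, floor(length(temp) / 10))
  bl <- lm(f[pre] ~ temp[pre])
  corr <- f - (coef(bl)[1] + coef(bl)[2] * temp)
  norm <- corr / max(corr)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      norm ~ lo + (hi - lo) / (1 + exp(-(temp - tm) / sc)),
      start = list(lo = min(norm), hi = max(norm), tm = t_mid,
                   sc = width / 2),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("sigmoid fit failed: ", conditionMessage(e)))
  cf <- coef(fit)
  if (cf[["tm"]] < min(temp) || cf[["tm"]] > max(temp)) {
    stop("fitted Tm outside the measured range; no usable transition")
  }
  data.frame(tm_C = cf[["tm"]], steepness_C = cf[["sc"]],
             rss = sum(stats::residuals(fit)^2))
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("melt_fit: Tm = %.2f +/- %.2f C (%d replicate%s)\n",
              x$tm_mean_C, x$tm_sd_C, nrow(x$replicates),
              if (nrow(x$replicates) > 1) "s" else ""))
  invisible(x)
}

#' @export
coef.melt_fit <- function(object, ...) {
  c(tm_C = object$tm_mean_C, tm_sd_C = object$tm_sd_C)
}

#' Read / write melt-curve CSV
#'
#' @param curve a \code{melt_curve}.
#' @param path file path.
#' @return \code{read_melt_csv} returns a \code{melt_curve}.
#' @export
write_melt_csv <- function(curve, path) {
  write.csv(data.frame(temperature_C = curve$temperature_C,
                       fluorescence = curve$fluorescence),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_melt_csv
#' @export
read_melt_csv <- function(path) {
  df <- read.csv(path)
  structure(list(temperature_C = df$temperature_C,
                 fluorescence = df$fluorescence),
            class = "melt_curve")
}
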