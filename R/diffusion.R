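#' Einstein-relation diffusion coefficient from an MSD series
#'
#' Ordinary least squares of `MSD = 6 D t + c` over a window of lag times.
#' In three dimensions the diffusive regime has MSD slope `6 D`; the
#' intercept `c` absorbs short-time (ballistic/caging) behaviour.  The
#' default window keeps lags between 10 and 50 percent of the largest lag:
#' short lags are dominated by the intercept, long lags by origin-starved
#' noise.
#'
#' @param series An [compute_msd()] series.
#' @param fit_window Length-2 numeric, fractions of the largest lag time
#'   bounding the fitted lags (default `c(0.1, 0.5)`).
#' @return An object of class `diffusion_fit`: list with
#'   `diffusion_coefficient` (m^2/s), `intercept` (m^2), `slope_stderr`
#'   mapped to `D_stderr` (m^2/s), `fit_window`, `n_points`, the underlying
#'   `lm` fit and the series.
#' @export
#' @examples
#' tr <- gen_brownian(100, 4.4e-9, timestep = 1000, n_frames = 500, seed = 5)
#' fit <- fit_diffusion(compute_msd(tr, "particle"))
#' fit
#' coef(fit)
fit_diffusion <- function(series, fit_window = c(0.1, 0.5)) {
  if (!inherits(series, "msd_series"))
    stop("'series' must be an msd_series", call. = FALSE)
  if (length(fit_window) != 2L || fit_window[1] >= fit_window[2] ||
      fit_window[1] < 0 || fit_window[2] > 1)
    stop("'fit_window' must be increasing fractions within [0, 1]",
         call. = FALSE)
  t <- series$lag_times
  tmax <- max(t)
  sel <- t >= fit_window[1] * tmax & t <= fit_window[2] * tmax
  if (sum(sel) < 2L)
    stop("fewer than 2 lag points fall inside the fit window", call. = FALSE)
  df <- data.frame(t = t[sel], msd = series$msd[sel])
  fit <- stats::lm(msd ~ t, data = df)
  # noiseless series trip summary.lm's perfect-fit warning; harmless here
  sl <- suppressWarnings(summary(fit))$coefficients
  slope_se <- if (nrow(sl) == 2L && !is.na(sl["t", "Std. Error"]))
    sl["t", "Std. Error"] else NA_real_
  structure(list(diffusion_coefficient = unname(stats::coef(fit)["t"]) / 6,
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 D_stderr = slope_se / 6,
                 fit_window = fit_window, n_points = sum(sel),
                 lm = fit, series = series),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("Einstein-relation fit (window %.0f-%.0f%% of max lag, %d points)\n",
              100 * x$fit_window[1], 100 * x$fit_window[2], x$n_points))
  cat(sprintf("  D = %.4g m^2/s  (se %.2g)\n",
              x$diffusion_coefficient, x$D_stderr))
  cat(sprintf("  intercept c = %.4g m^2\n", x$intercept))
  invisible(x)
}

#' @export
summary.diffusion_fit <- function(object, ...) {
  cat(sprintf("Diffusion coefficient for species '%s'\n",
              object$series$species))
  print(object)
  cat("\nUnderlying linear fit:\n")
  print(summary(object$lm))
  invisible(object)
}

#' @export
coef.diffusion_fit <- function(object, ...) {
  c(D = object$diffusion_coefficient, intercept = object$intercept)
}

#' @export
predict.diffusion_fit <- function(object, lag_times = NULL, ...) {
  if (is.null(lag_times)) lag_times <- object$series$lag_times
  6 * object$diffusion_coefficient * lag_times + object$intercept
}

#' @export
residuals.diffusion_fit <- function(object, ...) {
  stats::residuals(object$lm)
}

#' @export
plot.diffusion_fit <- function(x, ...) {
  s <- x$series
  graphics::plot(s$lag_times, s$msd, type = "l",
                 xlab = "lag time (s)", ylab = "MSD (m^2)",
                 main = sprintf("MSD fit: D = %.3g m^2/s",
                                x$diffusion_coefficient), ...)
  tmax <- max(s$lag_times)
  graphics::abline(v = x$fit_window * tmax, lty = 3, col = "grey60")
  graphics::lines(s$lag_times, predict(x), col = "red3", lty = 2)
  invisible(x)
}
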