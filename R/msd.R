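#' Time-origin-averaged mean square displacement
#'
#' For every lag `k * dt` up to `max_lag_fraction` of the trajectory length,
#' averages the squared displacement `|r(t0 + k dt) - r(t0)|^2` over all
#' particles of the selected species and all time origins `t0` on the
#' stride grid.  With `origin_stride = 1` (every origin) the computation
#' uses the FFT autocorrelation algorithm, which is exactly equivalent to
#' the direct double loop but `O(F log F)` per particle instead of
#' `O(F^2)`; larger strides use the direct strided average.
#'
#' Wrapped trajectories are refused: displacement across a periodic wrap is
#' ambiguous without image flags, so the MSD must be computed from
#' unwrapped coordinates (as produced by [gen_brownian()]).
#'
#' @param traj An unwrapped [trajectory()] with at least 3 uniformly spaced
#'   frames.
#' @param species Species label to analyse.
#' @param max_lag_fraction Largest lag as a fraction of the trajectory
#'   length (default 0.5; longer lags average too few origins to be
#'   useful).
#' @param origin_stride Spacing of time origins in frames (default 1 =
#'   every frame; overlapping windows are allowed).
#' @return An object of class `msd_series`: `lag_times` (s), `msd` (m^2),
#'   `n_origins_used`, plus metadata.  Lag 0 is implied and excluded.
#' @export
#' @examples
#' tr <- gen_brownian(50, 1e-9, timestep = 1000, n_frames = 400, seed = 4)
#' ms <- compute_msd(tr, "particle")
#' fit_diffusion(ms)
compute_msd <- function(traj, species, max_lag_fraction = 0.5,
                        origin_stride = 1) {
  if (!inherits(traj, "trajectory"))
    stop("'traj' must be a trajectory", call. = FALSE)
  if (isTRUE(traj$wrapped))
    stop("trajectory is wrapped: mean square displacement needs unwrapped ",
         "coordinates (periodic jumps would corrupt displacements); ",
         "re-run the generator or reader in unwrapped mode", call. = FALSE)
  nf <- n_frames(traj)
  if (nf < 3L) stop("need at least 3 frames", call. = FALSE)
  if (max_lag_fraction <= 0 || max_lag_fraction > 1)
    stop("'max_lag_fraction' must be in (0, 1]", call. = FALSE)
  origin_stride <- as.integer(origin_stride)
  if (origin_stride < 1L) stop("'origin_stride' must be >= 1", call. = FALSE)
  dt_s <- uniform_timestep(traj) * .fs_s
  idx <- species_index(traj, species)
  max_lag <- max(1L, floor(max_lag_fraction * (nf - 1L)))

  X <- traj$coords[idx, , , drop = FALSE] * .ang_m  # n x 3 x F, metres
  n <- length(idx)

  if (origin_stride == 1L) {
    res <- msd_fft_all_origins(X, max_lag)
    msd <- res$msd
    n_orig <- res$n_origins
  } else {
    msd <- numeric(max_lag)
    n_orig <- integer(max_lag)
    for (k in seq_len(max_lag)) {
      t0 <- seq.int(1L, nf - k, by = origin_stride)
      A <- X[, , t0 + k, drop = FALSE] - X[, , t0, drop = FALSE]
      msd[k] <- sum(A * A) / (n * length(t0))
      n_orig[k] <- length(t0)
    }
  }

  structure(list(lag_times = seq_len(max_lag) * dt_s, msd = msd,
                 n_origins_used = n_orig, species = species,
                 n_particles = n, timestep_s = dt_s),
            class = "msd_series")
}

# FFT route to the all-origins MSD.  For one signal x_t (t = 1..F) and lag k:
#   sum_t (x_{t+k} - x_t)^2 = SS(k) - 2 C(k),
#   SS(k) = sum_{t<=F-k} x_t^2 + sum_{t>k} x_t^2   (cumulative sums),
#   C(k)  = sum_t x_t x_{t+k}                      (autocorrelation, FFT).
# Signals are the per-particle per-axis coordinate series, centred per
# signal for numerical conditioning (MSD is translation invariant).
msd_fft_all_origins <- function(X, max_lag, chunk = 192L) {
  n <- dim(X)[1]; F <- dim(X)[3]
  sig <- matrix(aperm(X, c(3, 1, 2)), nrow = F)   # F x (n*3), axis-major
  sig <- sweep(sig, 2L, colMeans(sig))
  M <- 2^ceiling(log2(2 * F))
  total <- numeric(max_lag)
  nsig <- ncol(sig)
  for (j0 in seq(1L, nsig, by = chunk)) {
    j1 <- min(j0 + chunk - 1L, nsig)
    block <- sig[, j0:j1, drop = FALSE]
    pad <- rbind(block, matrix(0, M - F, ncol(block)))
    ft <- stats::mvfft(pad)
    ac <- Re(stats::mvfft(ft * Conj(ft), inverse = TRUE)) / M
    C <- ac[2:(max_lag + 1L), , drop = FALSE]     # C(k), k = 1..max_lag
    q <- block^2
    cs <- apply(q, 2L, cumsum)
    Q <- cs[F, ]
    k <- seq_len(max_lag)
    # SS(k) per column: cs[F-k] + Q - cs[k]
    SS <- cs[F - k, , drop = FALSE] +
      rep(Q, each = max_lag) - cs[k, , drop = FALSE]
    total <- total + rowSums(SS - 2 * C)
  }
  list(msd = total / (n * (F - seq_len(max_lag))),
       n_origins = F - seq_len(max_lag))
}

#' @export
print.msd_series <- function(x, ...) {
  cat(sprintf("MSD series for species '%s': %d lags up to %.4g s (%d particles)\n",
              x$species, length(x$msd), max(x$lag_times), x$n_particles))
  cat(sprintf("  MSD at max lag: %.4g m^2 (%d origins)\n",
              x$msd[length(x$msd)], x$n_origins_used[length(x$msd)]))
  invisible(x)
}

#' @export
plot.msd_series <- function(x, ...) {
  graphics::plot(x$lag_times, x$msd, type = "l",
                 xlab = "lag time (s)", ylab = "MSD (m^2)",
                 main = sprintf("Mean square displacement: %s", x$species),
                 ...)
  invisible(x)
}
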