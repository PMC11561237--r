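#' Brownian-walker trajectory with known diffusion coefficient
#'
#' Generates independent Gaussian random walks: each particle takes per-axis
#' steps of variance exactly `2 * D * dt` (dt converted to seconds), so the
#' ensemble mean square displacement is `6 D t` by construction and the
#' Einstein-relation machinery ([compute_msd()], [fit_diffusion()]) can be
#' validated against the input `D`.  The trajectory is unwrapped — particles
#' drift out of the box — which is exactly what displacement analysis needs.
#'
#' @param n_particles Number of independent walkers.
#' @param diffusion_coefficient Ground-truth D, m^2/s (`>= 0`).
#' @param timestep Step size, femtoseconds.
#' @param n_frames Number of stored frames (`>= 2`); frame 1 is the start.
#' @param box A [periodic_box()]; starting positions are uniform in it.
#' @param seed RNG seed; identical seeds give identical trajectories.
#' @return An unwrapped [trajectory()] with all particles labelled
#'   `"particle"`.
#' @export
#' @examples
#' tr <- gen_brownian(10, 4.4e-9, timestep = 1000, n_frames = 100, seed = 1)
#' tr
gen_brownian <- function(n_particles, diffusion_coefficient, timestep,
                         n_frames, box = periodic_box(21.2), seed = 1) {
  if (n_particles < 1L) stop("need at least one particle", call. = FALSE)
  if (n_frames < 2L) stop("need at least two frames", call. = FALSE)
  if (diffusion_coefficient < 0)
    stop("diffusion coefficient must be non-negative", call. = FALSE)
  box <- as_periodic_box(box)
  sd_ang <- sqrt(2 * diffusion_coefficient * timestep * .fs_s) / .ang_m
  coords <- with_local_seed(seed, {
    start <- matrix(stats::runif(n_particles * 3) * rep(box, each = n_particles),
                    n_particles, 3L)
    steps <- array(stats::rnorm(n_particles * 3 * (n_frames - 1L), sd = sd_ang),
                   c(n_particles, 3L, n_frames - 1L))
    out <- array(0, c(n_particles, 3L, n_frames))
    out[, , 1L] <- start
    acc <- start
    for (k in seq_len(n_frames - 1L)) {
      acc <- acc + steps[, , k]
      out[, , k + 1L] <- acc
    }
    out
  })
  trajectory(box, rep("particle", n_particles), coords,
             timestep = timestep, wrapped = FALSE)
}

#' Ideal-gas (uniform) configurations
#'
#' Every frame places all particles independently and uniformly in the box:
#' the null model for pair structure, whose radial distribution function is
#' identically 1.  Used to validate the [compute_rdf()] normalisation.
#'
#' @param n_particles Particle count (`>= 2`).
#' @param box A [periodic_box()].
#' @param n_frames Number of independent frames.
#' @param seed RNG seed.
#' @return A wrapped [trajectory()] with species `"gas"`.
#' @export
gen_ideal_gas <- function(n_particles, box, n_frames = 1, seed = 1) {
  if (n_particles < 2L) stop("need at least two particles", call. = FALSE)
  box <- as_periodic_box(box)
  coords <- with_local_seed(seed, {
    array(stats::runif(n_particles * 3 * n_frames) *
            rep(box, each = n_particles), c(n_particles, 3L, n_frames))
  })
  trajectory(box, rep("gas", n_particles), coords, timestep = 1,
             wrapped = TRUE)
}

#' Dimer gas with a fixed pair separation
#'
#' Places `n_pairs` two-particle dimers: one member (`species "A"`) uniform
#' in the box, its partner (`species "B"`) at exactly `separation` in a
#' uniformly random direction.  The A-B radial distribution function then
#' has a delta-like peak in the bin containing `separation`, which makes
#' this the canonical fixture for [first_peak()].  Note dimer centres are
#' *not* kept far apart, so at high pair density the background between
#' peaks is nonzero.
#'
#' @param n_pairs Number of dimers.
#' @param separation Intra-dimer distance, angstrom; must be below half the
#'   shortest box edge.
#' @param box A [periodic_box()].
#' @param seed RNG seed.
#' @return A wrapped single-frame [trajectory()] with `2 * n_pairs`
#'   particles, species `"A"` and `"B"`.
#' @export
gen_pair_gas <- function(n_pairs, separation, box, seed = 1) {
  box <- as_periodic_box(box)
  if (separation >= min(box) / 2)
    stop("separation must be below half the shortest box edge (",
         min(box) / 2, " angstrom)", call. = FALSE)
  if (n_pairs < 1L) stop("need at least one pair", call. = FALSE)
  coords <- with_local_seed(seed, {
    a <- matrix(stats::runif(n_pairs * 3) * rep(box, each = n_pairs),
                n_pairs, 3L)
    # isotropic random unit vectors
    u <- matrix(stats::rnorm(n_pairs * 3), n_pairs, 3L)
    u <- u / sqrt(rowSums(u^2))
    b <- wrap_positions(a + separation * u, box)
    rbind(a, b)
  })
  trajectory(box, c(rep("A", n_pairs), rep("B", n_pairs)), coords,
             timestep = 1, wrapped = TRUE)
}
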