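#' Particle trajectory in a periodic box
#'
#' The central container of the package: an ordered set of frames of labelled
#' particle positions in an orthorhombic periodic cell.  Coordinates are in
#' angstrom, times in femtoseconds.  The species ordering is fixed across
#' frames, so coordinates live in one `n_particles x 3 x n_frames` array.
#'
#' @param box A [periodic_box()] (or edge lengths coercible to one).
#' @param species Character vector of per-particle labels, e.g. `"O_water"`,
#'   `"H_water"`, `"O_OHcurcumin"`.  Free-form; selections elsewhere match
#'   these labels exactly.
#' @param coords Numeric array `n_particles x 3 x n_frames` (angstrom), or an
#'   `n x 3` matrix for a single frame.
#' @param times Numeric vector of frame times in femtoseconds, strictly
#'   increasing.  Defaults to `0, timestep, 2*timestep, ...`.
#' @param timestep Spacing between stored frames, femtoseconds.  Inferred
#'   from `times` when those are given.
#' @param wrapped Logical flag: are coordinates wrapped into the box?
#'   Structure analysis ([compute_rdf()]) wraps internally; displacement
#'   analysis ([compute_msd()]) refuses wrapped input.
#' @return An object of class `trajectory` with elements `box`, `species`,
#'   `coords`, `times`, `timestep`, `wrapped`.
#' @export
#' @examples
#' tr <- trajectory(periodic_box(10), c("A", "A"),
#'                  array(0, c(2, 3, 4)), timestep = 10)
#' tr
trajectory <- function(box, species, coords, times = NULL, timestep = 1,
                       wrapped = FALSE) {
  box <- as_periodic_box(box)
  species <- as.character(species)
  if (is.matrix(coords)) coords <- array(coords, c(dim(coords), 1L))
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    stop("'coords' must be an n_particles x 3 x n_frames array", call. = FALSE)
  n <- dim(coords)[1]
  nf <- dim(coords)[3]
  if (nf < 1L) stop("a trajectory needs at least one frame", call. = FALSE)
  if (length(species) != n)
    stop("'species' length (", length(species),
         ") does not match particle count (", n, ")", call. = FALSE)
  if (!all(is.finite(coords)))
    stop("coordinates must all be finite", call. = FALSE)
  if (is.null(times)) {
    if (!is.finite(timestep) || timestep <= 0)
      stop("'timestep' must be positive", call. = FALSE)
    times <- (seq_len(nf) - 1) * timestep
  } else {
    if (length(times) != nf)
      stop("'times' length does not match frame count", call. = FALSE)
    if (nf > 1L && any(diff(times) <= 0))
      stop("frame times must be strictly increasing", call. = FALSE)
    timestep <- if (nf > 1L) times[2] - times[1] else timestep
  }
  structure(list(box = box, species = species, coords = coords,
                 times = as.numeric(times), timestep = timestep,
                 wrapped = isTRUE(wrapped)),
            class = "trajectory")
}

n_frames <- function(traj) dim(traj$coords)[3]
n_particles <- function(traj) dim(traj$coords)[1]

# Coordinates of one frame as an n x 3 matrix.
frame_coords <- function(traj, i) {
  traj$coords[, , i, drop = FALSE][, , 1, drop = TRUE]
}

# Indices of particles with a given species label; errors if absent.
species_index <- function(traj, label) {
  idx <- which(traj$species == label)
  if (length(idx) == 0L)
    stop("species '", label, "' not present in trajectory (present: ",
         paste(unique(traj$species), collapse = ", "), ")", call. = FALSE)
  idx
}

# Uniform frame spacing in fs; errors when spacing is irregular.
uniform_timestep <- function(traj, tol = 1e-8) {
  if (n_frames(traj) < 2L) return(traj$timestep)
  dt <- diff(traj$times)
  if (diff(range(dt)) > tol * max(dt))
    stop("trajectory frames are not uniformly spaced in time", call. = FALSE)
  dt[1]
}

#' @export
print.trajectory <- function(x, ...) {
  sp <- table(x$species)
  cat(sprintf("Trajectory: %d particles, %d frame(s), dt = %g fs, %s\n",
              n_particles(x), n_frames(x), x$timestep,
              if (x$wrapped) "wrapped" else "unwrapped"))
  cat(sprintf("  box: %.3f x %.3f x %.3f angstrom\n",
              x$box[1], x$box[2], x$box[3]))
  cat("  species:", paste(sprintf("%s (%d)", names(sp), sp), collapse = ", "),
      "\n")
  invisible(x)
}

# Deep equality of two trajectories at a coordinate tolerance; used by the
# I/O round-trip machinery and tests.
trajectories_equal <- function(a, b, tol = 1e-6) {
  isTRUE(all.equal(as.numeric(a$box), as.numeric(b$box), tolerance = tol)) &&
    identical(a$species, b$species) &&
    identical(dim(a$coords), dim(b$coords)) &&
    max(abs(a$coords - b$coords)) <= tol &&
    isTRUE(all.equal(a$times, b$times, tolerance = tol)) &&
    identical(a$wrapped, b$wrapped)
}
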