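#' Read a multi-frame XYZ trajectory
#'
#' Reads the package's extended XYZ dialect.  Each frame is
#' ```
#'   <n_atoms>
#'   box=Lx,Ly,Lz t=<time_fs> [wrapped=0|1]
#'   <species> <x> <y> <z>     (n_atoms lines, angstrom)
#' ```
#' Plain XYZ carries no cell record, and the structure analysis needs one,
#' so the comment line is required to hold the box edges and frame time.
#'
#' @param path Path to an XYZ file.
#' @return A [trajectory()].
#' @seealso [write_xyz()] for the writer that produces this dialect.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  # drop trailing blank lines only
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (!length(lines)) stop("empty XYZ file: ", path, call. = FALSE)

  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      stop("malformed atom-count line ", i, " in ", path, call. = FALSE)
    if (i + 1L + n > length(lines))
      stop("truncated frame starting at line ", i, " in ", path, call. = FALSE)
    comment <- lines[i + 1L]
    box_m <- regmatches(comment,
                        regexec("box=([-0-9.eE+]+),([-0-9.eE+]+),([-0-9.eE+]+)",
                                comment))[[1]]
    if (length(box_m) != 4L)
      stop("missing or malformed box record on line ", i + 1L, " in ", path,
           call. = FALSE)
    t_m <- regmatches(comment, regexec("t=([-0-9.eE+]+)", comment))[[1]]
    if (length(t_m) != 2L)
      stop("missing time record on line ", i + 1L, " in ", path, call. = FALSE)
    w_m <- regmatches(comment, regexec("wrapped=([01])", comment))[[1]]
    atom_lines <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(atom_lines), "[[:space:]]+")
    if (any(lengths(parts) < 4L))
      stop("malformed atom line near line ", i + 1L + which(lengths(parts) < 4L)[1],
           " in ", path, call. = FALSE)
    sp <- vapply(parts, `[[`, "", 1L)
    xyz <- vapply(parts, function(p) as.numeric(p[2:4]), numeric(3))
    if (anyNA(xyz))
      stop("non-numeric coordinate in frame starting at line ", i, " in ",
           path, call. = FALSE)
    frames[[length(frames) + 1L]] <- list(
      n = n, box = as.numeric(box_m[2:4]), time = as.numeric(t_m[2]),
      wrapped = length(w_m) == 2L && w_m[2] == "1",
      species = sp, coords = t(xyz))
    i <- i + 2L + n
  }

  n0 <- frames[[1]]$n
  for (k in seq_along(frames)) {
    if (frames[[k]]$n != n0)
      stop("inconsistent particle count across frames: frame ", k, " has ",
           frames[[k]]$n, ", frame 1 has ", n0, call. = FALSE)
    if (!identical(frames[[k]]$species, frames[[1]]$species))
      stop("species ordering differs between frame ", k, " and frame 1",
           call. = FALSE)
  }
  coords <- array(unlist(lapply(frames, `[[`, "coords")), c(n0, 3L, length(frames)))
  trajectory(periodic_box(frames[[1]]$box), frames[[1]]$species, coords,
             times = vapply(frames, `[[`, 0, "time"),
             wrapped = frames[[1]]$wrapped)
}

#' Write a trajectory as multi-frame XYZ
#'
#' Writes the dialect documented in [read_xyz()]; coordinates are printed
#' with 6 decimals, so a read-back reproduces the trajectory to that
#' precision.
#'
#' @param traj A [trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  if (!inherits(traj, "trajectory"))
    stop("'traj' must be a trajectory object", call. = FALSE)
  n <- n_particles(traj)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_frames(traj))) {
    writeLines(as.character(n), con)
    writeLines(sprintf("box=%.6f,%.6f,%.6f t=%.6f wrapped=%d",
                       traj$box[1], traj$box[2], traj$box[3],
                       traj$times[k], as.integer(traj$wrapped)), con)
    xyz <- frame_coords(traj, k)
    writeLines(sprintf("%s %.6f %.6f %.6f", traj$species,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}
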