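#' Read a LAMMPS text dump
#'
#' Parses the plain-text LAMMPS dump dialect with sections
#' `ITEM: TIMESTEP`, `ITEM: NUMBER OF ATOMS`, `ITEM: BOX BOUNDS` (orthorhombic
#' only) and `ITEM: ATOMS id type x y z`.  Atoms are re-ordered by id within
#' every frame, so the particle ordering is stable even when the engine
#' writes them in a frame-dependent order.  Triclinic bounds (`xy xz yz`
#' tilt factors) are rejected.
#'
#' @param path Path to a dump file.
#' @param type_map Named character vector mapping numeric atom types to
#'   species labels, e.g. `c("1" = "O_water", "2" = "H_water")`.  Every type
#'   appearing in the file must be mapped.
#' @param timestep_fs Simulation time per dump step, femtoseconds (frame
#'   times are `TIMESTEP * timestep_fs`).
#' @return A [trajectory()] with `wrapped = TRUE` (dumps hold in-box
#'   coordinates).
#' @export
read_lammps_dump <- function(path, type_map, timestep_fs = 1) {
  if (is.null(names(type_map)) || any(!nzchar(names(type_map))))
    stop("'type_map' must be a named vector: names are type ids", call. = FALSE)
  lines <- readLines(path)
  item_idx <- grep("^ITEM: TIMESTEP", lines)
  if (!length(item_idx)) stop("not a LAMMPS dump: ", path, call. = FALSE)

  frames <- list()
  for (s in seq_along(item_idx)) {
    i <- item_idx[s]
    end <- if (s < length(item_idx)) item_idx[s + 1] - 1L else length(lines)
    blk <- lines[i:end]
    step <- as.numeric(trimws(blk[2]))
    na_at <- grep("^ITEM: NUMBER OF ATOMS", blk)
    bb_at <- grep("^ITEM: BOX BOUNDS", blk)
    at_at <- grep("^ITEM: ATOMS", blk)
    if (!length(na_at) || !length(bb_at) || !length(at_at))
      stop("malformed dump frame at line ", i, " in ", path, call. = FALSE)
    if (grepl("xy xz yz", blk[bb_at]))
      stop("triclinic box bounds are not supported (frame at line ", i, ")",
           call. = FALSE)
    n <- as.integer(trimws(blk[na_at + 1L]))
    bounds <- do.call(rbind, lapply(blk[bb_at + 1:3], function(l)
      as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]])))
    if (anyNA(bounds) || ncol(bounds) != 2L)
      stop("malformed BOX BOUNDS at line ", i, " in ", path, call. = FALSE)
    cols <- strsplit(sub("^ITEM: ATOMS[[:space:]]*", "", blk[at_at]),
                     "[[:space:]]+")[[1]]
    need <- c("id", "type", "x", "y", "z")
    if (!all(need %in% cols))
      stop("dump must provide columns id type x y z (got: ",
           paste(cols, collapse = " "), ")", call. = FALSE)
    rows <- blk[(at_at + 1L):(at_at + n)]
    m <- matrix(as.numeric(unlist(strsplit(trimws(rows), "[[:space:]]+"))),
                nrow = n, byrow = TRUE)
    colnames(m) <- cols
    m <- m[order(m[, "id"]), , drop = FALSE]
    types <- as.character(as.integer(m[, "type"]))
    unknown <- setdiff(unique(types), names(type_map))
    if (length(unknown))
      stop("atom type(s) ", paste(unknown, collapse = ", "),
           " have no species mapping", call. = FALSE)
    frames[[s]] <- list(step = step, n = n,
                        box = bounds[, 2] - bounds[, 1],
                        species = unname(type_map[types]),
                        coords = m[, c("x", "y", "z"), drop = FALSE])
  }
  frames <- frames[order(vapply(frames, `[[`, 0, "step"))]
  n0 <- frames[[1]]$n
  for (k in seq_along(frames)) {
    if (frames[[k]]$n != n0)
      stop("inconsistent atom count across dump frames", call. = FALSE)
    if (!identical(frames[[k]]$species, frames[[1]]$species))
      stop("atom types differ across dump frames after id ordering",
           call. = FALSE)
  }
  coords <- array(unlist(lapply(frames, `[[`, "coords")), c(n0, 3L, length(frames)))
  trajectory(periodic_box(frames[[1]]$box), frames[[1]]$species, coords,
             times = vapply(frames, `[[`, 0, "step") * timestep_fs,
             wrapped = TRUE)
}
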