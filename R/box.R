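#' Orthorhombic periodic box
#'
#' Constructs a periodic simulation cell from its three edge lengths.  Only
#' orthorhombic (right-angled) cells are supported; triclinic cells are
#' rejected wherever they could enter (see [read_lammps_dump()]).
#'
#' @param edge_lengths Numeric vector of three strictly positive edge
#'   lengths in angstrom.  A single value is recycled to a cubic box.
#' @return An object of class `periodic_box`: a length-3 numeric vector of
#'   edge lengths (angstrom).
#' @export
#' @examples
#' periodic_box(21.2)            # cubic, like a typical solvation cell
#' periodic_box(c(20, 30, 40))
periodic_box <- function(edge_lengths) {
  if (length(edge_lengths) == 1L) edge_lengths <- rep(edge_lengths, 3L)
  if (length(edge_lengths) != 3L)
    stop("'edge_lengths' must have length 1 or 3", call. = FALSE)
  edge_lengths <- as.numeric(edge_lengths)
  if (!all(is.finite(edge_lengths)) || any(edge_lengths <= 0))
    stop("box edge lengths must be finite and strictly positive", call. = FALSE)
  structure(edge_lengths, class = "periodic_box")
}

#' @export
print.periodic_box <- function(x, ...) {
  cat(sprintf("Orthorhombic periodic box: %.4f x %.4f x %.4f angstrom\n",
              x[1], x[2], x[3]))
  invisible(x)
}

as_periodic_box <- function(x) {
  if (inherits(x, "periodic_box")) x else periodic_box(x)
}

#' Minimum-image convention for displacements
#'
#' Maps each component of a displacement vector into `(-L/2, L/2]` for the
#' corresponding box edge `L`, i.e. replaces the displacement by the one to
#' the nearest periodic image.  Works on a single 3-vector or on an
#' `n x 3` matrix of displacements.
#'
#' @param displacement Numeric 3-vector or `n x 3` matrix, angstrom.
#' @param box A [periodic_box()] (or coercible edge lengths).
#' @return Object of the same shape with every component in `(-L/2, L/2]`.
#' @export
#' @examples
#' minimum_image(c(9, 0, 0), periodic_box(10))   # -> c(-1, 0, 0)
#' minimum_image(c(-5, 5, 15), periodic_box(10)) # -> c(5, 5, 5)
minimum_image <- function(displacement, box) {
  box <- as_periodic_box(box)
  if (is.matrix(displacement)) {
    if (ncol(displacement) != 3L)
      stop("displacement matrix must have 3 columns", call. = FALSE)
    L <- rep(box, each = nrow(displacement))
  } else {
    if (length(displacement) != 3L)
      stop("displacement must be a 3-vector or an n x 3 matrix", call. = FALSE)
    L <- as.numeric(box)
  }
  # d - L*ceiling(d/L - 1/2) lands exactly in (-L/2, L/2]
  displacement - L * ceiling(displacement / L - 0.5)
}

# Wrap absolute coordinates into [0, L) per axis.
wrap_positions <- function(coords, box) {
  box <- as.numeric(as_periodic_box(box))
  if (is.matrix(coords)) {
    L <- rep(box, each = nrow(coords))
  } else L <- box
  coords - L * floor(coords / L)
}
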