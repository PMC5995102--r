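#' Construct a cast
#'
#' A cast is the result of projecting an indexed 2D template grid onto a 3D
#' surface: one row per grid point, identified by a stable integer `id`
#' (0-based, row-major over the template lattice). Points whose projection
#' ray missed the surface are kept with `valid = FALSE` so that ids stay
#' comparable across specimens.
#'
#' @param id integer vector of 0-based grid-point ids.
#' @param x,y,z coordinates in micrometres; `NA` allowed where `valid` is
#'   `FALSE`.
#' @param valid logical vector marking points that hit the surface.
#' @param n_rows,n_cols template lattice dimensions (optional, kept as
#'   attributes).
#' @return A tibble of class `mw_cast` with columns `id`, `x`, `y`, `z`,
#'   `valid`.
#' @export
new_cast <- function(id, x, y, z, valid = rep(TRUE, length(id)),
                     n_rows = NA_integer_, n_cols = NA_integer_) {
  stopifnot(length(x) == length(id), length(y) == length(id),
            length(z) == length(id), length(valid) == length(id))
  if (anyDuplicated(id)) abort("cast ids must be unique")
  out <- tibble(id = as.integer(id), x = as.numeric(x), y = as.numeric(y),
                z = as.numeric(z), valid = as.logical(valid))
  attr(out, "n_rows") <- as.integer(n_rows)
  attr(out, "n_cols") <- as.integer(n_cols)
  class(out) <- c("mw_cast", class(out))
  out
}

#' @export
print.mw_cast <- function(x, ...) {
  cat(sprintf("<cast: %d grid points, %d valid>\n", nrow(x), sum(x$valid)))
  NextMethod()
}

is_cast <- function(x) {
  is.data.frame(x) && all(c("id", "x", "y", "z", "valid") %in% names(x))
}

as_cast_df <- function(x, arg = "cast") {
  if (!is_cast(x)) abort(sprintf("`%s` must have columns id, x, y, z, valid", arg))
  x
}

valid_points <- function(cast) cast[cast$valid, , drop = FALSE]

#' Construct a triangle mesh
#'
#' @param vertices numeric matrix (n x 3) of vertex coordinates in
#'   micrometres, columns x, y, z.
#' @param faces integer matrix (m x 3) of 1-based vertex indices.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3) abort("vertices must be an n x 3 matrix")
  if (nrow(faces) > 0) {
    if (min(faces) < 1 || max(faces) > nrow(vertices))
      abort("face indices out of range")
    if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
              faces[, 2] == faces[, 3]))
      abort("faces must not repeat a vertex index")
  }
  colnames(vertices) <- c("x", "y", "z")
  structure(list(vertices = vertices, faces = faces),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh: %d vertices, %d faces>\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Construct an intensity volume
#'
#' A 3D scalar lattice (e.g. a confocal stack) stored as an array with
#' dimensions `(nz, ny, nx)` and anisotropic voxel spacing `(dz, dy, dx)`
#' in micrometres. World coordinates of voxel `(iz, iy, ix)` (1-based) are
#' `((ix-1)*dx, (iy-1)*dy, (iz-1)*dz)` for (x, y, z), with the z axis the
#' slice (projection) axis.
#'
#' @param voxels numeric 3D array, dims `(nz, ny, nx)`.
#' @param spacing numeric length-3, `(dz, dy, dx)` in micrometres.
#' @return An object of class `intensity_volume`.
#' @export
intensity_volume <- function(voxels, spacing) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) == 2) dim(voxels) <- c(1L, dim(voxels))
  if (length(dim(voxels)) != 3) abort("voxels must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    abort("spacing must be 3 positive numbers (dz, dy, dx)")
  if (any(!is.finite(voxels))) abort("intensities must be finite")
  structure(list(voxels = voxels, spacing = spacing),
            class = "intensity_volume")
}

#' @export
print.intensity_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<intensity_volume: %d x %d x %d (nz,ny,nx), spacing %.3g/%.3g/%.3g um>\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}
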