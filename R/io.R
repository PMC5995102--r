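#' Read a multi-page grayscale TIFF stack
#'
#' Loads a confocal (or other) image stack into an [intensity_volume()].
#' Voxel spacing supplied via `spacing` always wins over TIFF resolution
#' tags, which are unreliable in microscope exports; a mismatch is reported
#' as a message.
#'
#' @param path path to a multi-page grayscale TIFF.
#' @param spacing numeric length-3 `(dz, dy, dx)` in micrometres, or `NULL`
#'   to attempt recovery of `dx`/`dy` from TIFF resolution tags (the slice
#'   distance `dz` can never be recovered from baseline TIFF and must then
#'   fail).
#' @return An [intensity_volume()].
#' @export
read_stack <- function(path, spacing = NULL) {
  if (!file.exists(path)) abort(sprintf("stack file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2, logical(1))))
    abort("stack is not grayscale (pages have a channel dimension)")
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    abort("stack pages differ in size")
  tag_spacing <- NULL
  info <- attributes(pages[[1]])
  if (!is.null(info$x.resolution) && is.finite(info$x.resolution) &&
        info$x.resolution > 0) {
    unit_um <- switch(as.character(info$resolution.unit %||% "inch"),
                      inch = 25400, cm = 10000, 25400)
    tag_spacing <- c(unit_um / (info$y.resolution %||% info$x.resolution),
                     unit_um / info$x.resolution)
  }
  if (is.null(spacing)) {
    if (is.null(tag_spacing))
      abort("no voxel spacing supplied and none recoverable from TIFF tags")
    abort("TIFF tags carry no slice distance; supply spacing = c(dz, dy, dx)")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0))
    abort("spacing must be 3 positive numbers (dz, dy, dx)")
  if (!is.null(tag_spacing) &&
        any(abs(tag_spacing - spacing[2:3]) > 1e-6 * spacing[2:3]))
    inform("voxel spacing overrides differing TIFF resolution tags")
  vol <- aperm(array(unlist(pages, use.names = FALSE),
                     dim = c(dims[1, 1], dims[2, 1], length(pages))),
               c(3, 1, 2))
  if (any(vol < 0)) abort("negative intensities in stack")
  if (length(pages) == 1L) warn("single-slice stack: volume has depth 1")
  intensity_volume(vol, spacing)
}

#' Write / read a cast as an OBJ point file with an id sidecar
#'
#' Casts are point sets, so the OBJ carries vertex (`v`) lines only, one per
#' *valid* point. OBJ has no vertex naming, so grid-point ids are preserved
#' in a sidecar CSV (`<path>.idx.csv`) mapping each id to its 1-based vertex
#' line; invalid points are omitted from the OBJ and absent from the
#' sidecar, which is how they are recognised on re-import.
#'
#' @param cast a cast (see [new_cast()]) with at least one valid point.
#' @param path output OBJ path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_cast <- function(cast, path) {
  cast <- as_cast_df(cast)
  vp <- valid_points(cast)
  if (nrow(vp) == 0) abort("cast has no valid points")
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(c("# morphowrap cast",
               sprintf("v %.9f %.9f %.9f", vp$x, vp$y, vp$z)), con)
  side <- tibble(id = vp$id, line = seq_len(nrow(vp)))
  hdr <- sprintf("# grid %d %d %d",
                 attr(cast, "n_rows") %||% NA_integer_,
                 attr(cast, "n_cols") %||% NA_integer_, nrow(cast))
  side_path <- sidecar_path(path)
  writeLines(c(hdr, "id,line",
               sprintf("%d,%d", side$id, side$line)), side_path)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".idx.csv")

#' @rdname write_cast
#' @export
read_cast <- function(path) {
  if (!file.exists(path)) abort(sprintf("cast file not found: %s", path))
  side_path <- sidecar_path(path)
  if (!file.exists(side_path)) abort(sprintf("sidecar not found: %s", side_path))
  lines <- readLines(path)
  vlines <- lines[startsWith(lines, "v ")]
  coords <- do.call(rbind, lapply(strsplit(vlines, "[ ]+"), function(f) {
    v <- suppressWarnings(as.numeric(f[2:4]))
    if (any(is.na(v))) abort("malformed OBJ vertex line")
    v
  }))
  slines <- readLines(side_path)
  hdr <- slines[startsWith(slines, "# grid")]
  n_rows <- n_cols <- NA_integer_
  n_total <- nrow(coords)
  if (length(hdr) == 1) {
    f <- suppressWarnings(as.integer(strsplit(hdr, "[ ]+")[[1]][3:5]))
    n_rows <- f[1]; n_cols <- f[2]
    if (!is.na(f[3])) n_total <- f[3]
  }
  side <- read.csv(text = slines[!startsWith(slines, "#")])
  if (anyDuplicated(side$id)) abort("duplicate ids in sidecar")
  if (any(side$line < 1 | side$line > nrow(coords)))
    abort("sidecar references a missing vertex line")
  all_ids <- if (!is.na(n_rows) && !is.na(n_cols)) {
    0:(n_rows * n_cols - 1L)
  } else if (n_total >= length(side$id)) {
    sort(unique(c(side$id, seq_len(n_total) - 1L)))[seq_len(n_total)]
  } else side$id
  pos <- match(all_ids, side$id)
  xyz <- matrix(NA_real_, length(all_ids), 3)
  hit <- !is.na(pos)
  xyz[hit, ] <- coords[side$line[pos[hit]], , drop = FALSE]
  new_cast(all_ids, xyz[, 1], xyz[, 2], xyz[, 3], valid = hit,
           n_rows = n_rows, n_cols = n_cols)
}

#' Export a cast or mean model as a plain-text point table
#'
#' One row per valid point, columns `id, x, y, z` in micrometres with a
#' header line, ready for CAD, streamline or finite-element tools.
#'
#' @param model a cast or mean model (any data frame with `id, x, y, z` and
#'   optionally `valid`).
#' @param path output file path.
#' @param sep field separator: `","` (CSV, default) or `"\t"` (TSV).
#' @return `path`, invisibly.
#' @export
export_point_table <- function(model, path, sep = ",") {
  if (!all(c("id", "x", "y", "z") %in% names(model)))
    abort("model must have columns id, x, y, z")
  rows <- if ("valid" %in% names(model)) model[model$valid, ] else model
  if (nrow(rows) == 0) abort("empty model: no valid points to export")
  utils::write.table(rows[, c("id", "x", "y", "z")], path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a triangle mesh as Wavefront OBJ
#'
#' Minimal OBJ support: `v` and (triangular) `f` lines only.
#'
#' @param mesh a [triangle_mesh()].
#' @param path file path.
#' @return `write_mesh`: `path` invisibly; `read_mesh`: a [triangle_mesh()].
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  v <- mesh$vertices
  writeLines(c("# morphowrap mesh",
               sprintf("v %.9f %.9f %.9f", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                       mesh$faces[, 3])), path)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) abort(sprintf("mesh file not found: %s", path))
  lines <- readLines(path)
  vl <- strsplit(lines[startsWith(lines, "v ")], "[ ]+")
  fl <- strsplit(lines[startsWith(lines, "f ")], "[ ]+")
  verts <- do.call(rbind, lapply(vl, function(f) as.numeric(f[2:4])))
  faces <- do.call(rbind, lapply(fl, function(f) {
    as.integer(sub("/.*", "", f[2:4]))
  }))
  if (is.null(verts)) abort("no vertices in OBJ")
  triangle_mesh(verts, faces %||% matrix(integer(0), 0, 3))
}

#' Read landmark pairs for grid warping
#'
#' @param path CSV with columns
#'   `name,u_template,v_template,u_specimen,v_specimen` (micrometres).
#' @return A tibble of landmark pairs.
#' @export
read_landmark_pairs <- function(path) {
  df <- as_tibble(read.csv(path))
  need <- c("u_template", "v_template", "u_specimen", "v_specimen")
  if (!all(need %in% names(df)))
    abort("landmark file needs columns u_template, v_template, u_specimen, v_specimen")
  df
}

#' Study configuration
#'
#' Bundles the tunable parameters of the workflow with their defaults:
#' 5 um Gaussian blur, 15 um marching cube size, at most 2 smoothing passes,
#' a 400 x 320 (= 128,000 point) template grid, p threshold 0.01, q
#' threshold 0.005, 95% confidence ellipsoids and no size adjustment.
#'
#' @param blur_sigma_um Gaussian blur sd in micrometres.
#' @param cube_size_um iso-surface cube edge in micrometres.
#' @param smoothing_passes Laplacian smoothing passes (warns above 3).
#' @param grid_rows,grid_cols template lattice dimensions.
#' @param p_threshold,q_threshold significance thresholds.
#' @param ci_level confidence-ellipsoid level, in (0, 1).
#' @param allow_scaling logical; `TRUE` switches the Procrustes fit from
#'   partial (form-preserving) to full (size-removing).
#' @param seed integer RNG seed used by stochastic stages.
#' @param ... further fields kept verbatim (e.g. paths, simulate block).
#' @return A list of class `study_config`.
#' @export
study_config <- function(blur_sigma_um = 5, cube_size_um = 15,
                         smoothing_passes = 2, grid_rows = 400,
                         grid_cols = 320, p_threshold = 0.01,
                         q_threshold = 0.005, ci_level = 0.95,
                         allow_scaling = FALSE, seed = 1L, ...) {
  cfg <- list(blur_sigma_um = blur_sigma_um, cube_size_um = cube_size_um,
              smoothing_passes = smoothing_passes, grid_rows = grid_rows,
              grid_cols = grid_cols, p_threshold = p_threshold,
              q_threshold = q_threshold, ci_level = ci_level,
              allow_scaling = allow_scaling, seed = as.integer(seed), ...)
  num <- c("blur_sigma_um", "cube_size_um", "grid_rows", "grid_cols",
           "p_threshold", "q_threshold")
  for (f in num) if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
    abort(sprintf("config field %s must be positive", f))
  if (cfg$smoothing_passes < 0) abort("smoothing_passes must be >= 0")
  if (cfg$smoothing_passes > 3)
    warn("smoothing_passes exceeds recommended 3 passes (mesh shrinkage)")
  if (cfg$ci_level <= 0 || cfg$ci_level >= 1) abort("ci_level must be in (0,1)")
  if (cfg$grid_rows * cfg$grid_cols < 4) abort("grid must have at least 4 points")
  class(cfg) <- "study_config"
  cfg
}

#' @rdname study_config
#' @param path YAML file of configuration fields.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  do.call(study_config, yaml::read_yaml(path))
}

# line-oriented stage log (stderr, optionally tee'd to file)
mw_log <- function(stage, msg, logfile = NULL) {
  line <- sprintf("[%s] %-12s %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
  invisible(line)
}
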