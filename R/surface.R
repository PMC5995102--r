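#' Gaussian blur of an intensity volume
#'
#' Separable Gaussian smoothing with the kernel width given in micrometres
#' and converted per axis to voxel units through the volume's anisotropic
#' spacing, so the blur is isotropic in physical space. Boundaries are
#' handled by mirror reflection, which keeps specimens at stack edges from
#' being dimmed and conserves total intensity exactly for the symmetric
#' kernel.
#'
#' @param vol an [intensity_volume()].
#' @param sigma_um blur sd in micrometres; `0` returns the input unchanged.
#' @return An [intensity_volume()] with identical dims and spacing.
#' @export
gaussian_blur <- function(vol, sigma_um) {
  stopifnot(inherits(vol, "intensity_volume"))
  if (!is.numeric(sigma_um) || length(sigma_um) != 1 || sigma_um < 0)
    abort("sigma_um must be a single non-negative number")
  if (sigma_um == 0) return(vol)
  a <- vol$voxels
  for (d in 1:3) {
    sig_vox <- sigma_um / vol$spacing[d]
    a <- conv1_reflect(a, d, gauss_kernel(sig_vox))
  }
  intensity_volume(a, vol$spacing)
}

gauss_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# convolve a 3D array along dimension d with mirror-reflected boundaries
conv1_reflect <- function(a, d, kernel) {
  dm <- dim(a)
  perm <- c(d, setdiff(1:3, d))
  ap <- aperm(a, perm)
  n <- dm[d]
  m <- matrix(ap, nrow = n)
  r <- (length(kernel) - 1L) / 2L
  idx <- c(rev(seq_len(min(r, n))), seq_len(n), n + 1 - seq_len(min(r, n)))
  while (length(idx) < n + 2 * r) { # pathological: kernel wider than axis
    idx <- c(rev(idx[seq_len(min(r, length(idx)))]), idx)
    idx <- idx[seq_len(n + 2 * r)]
  }
  pad <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (k in seq_along(kernel))
    out <- out + kernel[k] * pad[(k - 1L) + seq_len(n), , drop = FALSE]
  aperm(array(out, dm[perm]), order(perm))
}

#' Extract an iso-surface mesh from an intensity volume
#'
#' The volume is first resampled by trilinear interpolation onto an
#' isotropic lattice of edge `cube_size_um`, then the iso-surface at
#' `threshold` is triangulated by marching tetrahedra: each lattice cube is
#' split into six tetrahedra sharing the main diagonal and every
#' threshold-crossing edge contributes a linearly interpolated vertex. The
#' decomposition has no ambiguous cases, so the output is deterministic.
#' Vertices are returned in micrometres in volume coordinates and welded
#' (duplicates merged) so the mesh is connected for smoothing.
#'
#' @param vol an [intensity_volume()].
#' @param threshold iso-surface intensity level.
#' @param cube_size_um isotropic resampling edge length in micrometres; must
#'   be at least the largest voxel spacing.
#' @return A [triangle_mesh()].
#' @export
extract_surface <- function(vol, threshold, cube_size_um) {
  stopifnot(inherits(vol, "intensity_volume"))
  if (cube_size_um < max(vol$spacing))
    abort("cube_size_um must be >= the largest voxel spacing")
  rng <- range(vol$voxels)
  if (threshold >= rng[2]) {
    if (threshold > rng[2]) warn("threshold above intensity range")
    abort("empty surface: no voxel above threshold")
  }
  if (threshold < rng[1]) warn("threshold below intensity range")
  a <- resample_isotropic(vol, cube_size_um)
  tris <- marching_tetrahedra(a, threshold, cube_size_um)
  if (nrow(tris) == 0) abort("empty surface: no voxel above threshold")
  weld_mesh(tris)
}

# trilinear resampling onto an isotropic grid of step h (um); returns array
resample_isotropic <- function(vol, h) {
  d <- dim(vol$voxels)
  sp <- vol$spacing
  ax <- lapply(1:3, function(k) seq(0, (d[k] - 1) * sp[k], by = h))
  nz <- length(ax[[1]]); ny <- length(ax[[2]]); nx <- length(ax[[3]])
  # fractional source indices (0-based)
  fz <- ax[[1]] / sp[1]; fy <- ax[[2]] / sp[2]; fx <- ax[[3]] / sp[3]
  iz0 <- pmin(floor(fz), d[1] - 2L); iz0 <- pmax(iz0, 0L)
  iy0 <- pmin(floor(fy), max(d[2] - 2L, 0L)); iy0 <- pmax(iy0, 0L)
  ix0 <- pmin(floor(fx), max(d[3] - 2L, 0L)); ix0 <- pmax(ix0, 0L)
  tz <- fz - iz0; ty <- fy - iy0; tx <- fx - ix0
  if (d[1] == 1L) { iz0[] <- 0L; tz[] <- 0 }
  if (d[2] == 1L) { iy0[] <- 0L; ty[] <- 0 }
  if (d[3] == 1L) { ix0[] <- 0L; tx[] <- 0 }
  G <- function(dz, dy, dx) {
    vol$voxels[cbind(
      rep(iz0 + 1L + dz, times = ny * nx),
      rep(rep(iy0 + 1L + dy, each = nz), times = nx),
      rep(ix0 + 1L + dx, each = nz * ny))]
  }
  d1 <- function(v, up) if (up) pmin(v, 1L) else v # clamp offsets on thin axes
  o <- function(dz, dy, dx) G(min(dz, d[1] - 1L), min(dy, d[2] - 1L),
                              min(dx, d[3] - 1L))
  Wz <- rep(tz, times = ny * nx); Wy <- rep(rep(ty, each = nz), times = nx)
  Wx <- rep(tx, each = nz * ny)
  v <- (1 - Wz) * (1 - Wy) * (1 - Wx) * o(0L, 0L, 0L) +
    Wz * (1 - Wy) * (1 - Wx) * o(1L, 0L, 0L) +
    (1 - Wz) * Wy * (1 - Wx) * o(0L, 1L, 0L) +
    (1 - Wz) * (1 - Wy) * Wx * o(0L, 0L, 1L) +
    Wz * Wy * (1 - Wx) * o(1L, 1L, 0L) +
    Wz * (1 - Wy) * Wx * o(1L, 0L, 1L) +
    (1 - Wz) * Wy * Wx * o(0L, 1L, 1L) +
    Wz * Wy * Wx * o(1L, 1L, 1L)
  array(v, c(nz, ny, nx))
}

# six-tetrahedra decomposition of the unit cube (corner bits: 1 = +z slice,
# 2 = +y, 4 = +x), all sharing the 0-7 main diagonal
TET_DECOMP <- rbind(c(0L, 5L, 1L, 7L), c(0L, 1L, 3L, 7L), c(0L, 3L, 2L, 7L),
                    c(0L, 2L, 6L, 7L), c(0L, 6L, 4L, 7L), c(0L, 4L, 5L, 7L))

# triangles (as inside->outside edge pairs) for each of the 14 crossing
# sign patterns of a tetrahedron's 4 vertices
tet_case_edges <- function(mask) {
  ins <- which(mask); outs <- which(!mask)
  if (length(ins) == 1) {
    list(rbind(c(ins, outs[1]), c(ins, outs[2]), c(ins, outs[3])))
  } else if (length(ins) == 3) {
    list(rbind(c(ins[1], outs), c(ins[2], outs), c(ins[3], outs)))
  } else if (length(ins) == 2) {
    a <- ins[1]; b <- ins[2]; c_ <- outs[1]; d_ <- outs[2]
    list(rbind(c(a, c_), c(a, d_), c(b, d_)),
         rbind(c(a, c_), c(b, d_), c(b, c_)))
  } else list()
}

TET_CASES <- lapply(0:15, function(code) {
  tet_case_edges(as.logical(bitwAnd(code, c(1L, 2L, 4L, 8L)) > 0))
})

marching_tetrahedra <- function(a, threshold, h) {
  d <- dim(a)
  if (any(d < 2)) abort("volume too thin for surface extraction")
  nz <- d[1] - 1L; ny <- d[2] - 1L; nx <- d[3] - 1L
  # flat index of every cube's base corner
  iz <- rep(seq_len(nz), times = ny * nx)
  iy <- rep(rep(seq_len(ny), each = nz), times = nx)
  ix <- rep(seq_len(nx), each = nz * ny)
  base <- iz + (iy - 1L) * d[1] + (ix - 1L) * d[1] * d[2]
  corner_off <- function(bit) {
    dz <- bitwAnd(bit, 1L); dy <- ifelse(bitwAnd(bit, 2L) > 0, 1L, 0L)
    dx <- ifelse(bitwAnd(bit, 4L) > 0, 1L, 0L)
    dz + dy * d[1] + dx * d[1] * d[2]
  }
  off <- vapply(0:7, corner_off, integer(1))
  av <- as.vector(a)
  cz <- (iz - 1L) * h; cy <- (iy - 1L) * h; cx <- (ix - 1L) * h
  # world coords of corner k relative to cube base, in (x, y, z)
  cpos <- function(bit, idx) {
    cbind(cx[idx] + ifelse(bitwAnd(bit, 4L) > 0, h, 0),
          cy[idx] + ifelse(bitwAnd(bit, 2L) > 0, h, 0),
          cz[idx] + bitwAnd(bit, 1L) * h)
  }
  tri_list <- list()
  for (t in seq_len(nrow(TET_DECOMP))) {
    corn <- TET_DECOMP[t, ]
    vals <- lapply(corn, function(b) av[base + off[b + 1L]])
    inside <- lapply(vals, function(v) v > threshold)
    code <- inside[[1]] + 2L * inside[[2]] + 4L * inside[[3]] + 8L * inside[[4]]
    for (cs in which(lengths(TET_CASES) > 0) - 1L) {
      sel <- which(code == cs)
      if (length(sel) == 0) next
      for (tri in TET_CASES[[cs + 1L]]) {
        pts <- lapply(1:3, function(e) {
          va <- vals[[tri[e, 1]]][sel]; vb <- vals[[tri[e, 2]]][sel]
          pa <- cpos(corn[tri[e, 1]], sel); pb <- cpos(corn[tri[e, 2]], sel)
          tt <- (threshold - va) / (vb - va)
          pa + tt * (pb - pa)
        })
        tri_list[[length(tri_list) + 1L]] <-
          cbind(pts[[1]], pts[[2]], pts[[3]])
      }
    }
  }
  if (length(tri_list) == 0) return(matrix(0, 0, 9))
  do.call(rbind, tri_list)
}

# merge duplicate vertices of a triangle soup (n x 9: p1 p2 p3) into a mesh
weld_mesh <- function(tris, digits = 9) {
  p <- rbind(tris[, 1:3, drop = FALSE], tris[, 4:6, drop = FALSE],
             tris[, 7:9, drop = FALSE])
  key <- paste(round(p[, 1], digits), round(p[, 2], digits),
               round(p[, 3], digits))
  uid <- match(key, key[!duplicated(key)])
  verts <- p[!duplicated(key), , drop = FALSE]
  n <- nrow(tris)
  faces <- cbind(uid[seq_len(n)], uid[n + seq_len(n)], uid[2 * n + seq_len(n)])
  keep <- faces[, 1] != faces[, 2] & faces[, 1] != faces[, 3] &
    faces[, 2] != faces[, 3]
  triangle_mesh(verts, faces[keep, , drop = FALSE])
}

#' Laplacian smoothing of a triangle mesh
#'
#' Each pass replaces every vertex by the unweighted average of its 1-ring
#' neighbours. Topology (faces, connectivity) is never changed. More than 3
#' passes triggers a warning because uniform Laplacian smoothing shrinks the
#' mesh.
#'
#' @param mesh a [triangle_mesh()].
#' @param passes non-negative integer; `0` is the identity.
#' @return A [triangle_mesh()] with the same faces.
#' @export
smooth_mesh <- function(mesh, passes) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (passes < 0 || passes != round(passes))
    abort("passes must be a non-negative integer")
  if (passes > 3) warn("exceeds recommended 3 passes: expect mesh shrinkage")
  if (passes == 0) return(mesh)
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- unique(rbind(e, e[, 2:1]))
  v <- mesh$vertices
  deg <- tabulate(e[, 1], nbins = nrow(v))
  if (any(deg == 0)) warn("isolated vertices left in place during smoothing")
  for (p in seq_len(passes)) {
    sums <- rowsum(v[e[, 2], , drop = FALSE], e[, 1])
    idx <- as.integer(rownames(sums))
    vn <- v
    vn[idx, ] <- sums / deg[idx]
    v <- vn
  }
  triangle_mesh(v, f)
}

#' Surface area of a triangle mesh
#'
#' @param mesh a [triangle_mesh()].
#' @return Total area in square micrometres.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}
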