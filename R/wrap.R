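#' Build the indexed 2D template grid
#'
#' A uniform lattice of `n_rows * n_cols` points filling `bbox`, the
#' template every cast of a study shares. Ids are 0-based, row-major: point
#' `(row, col)` (0-based) has `id = row * n_cols + col`; `u` varies along
#' columns and `v` along rows. The default study resolution is 400 x 320 =
#' 128,000 points.
#'
#' @param n_rows,n_cols lattice dimensions, both at least 2.
#' @param bbox numeric length-4 `(umin, umax, vmin, vmax)` in micrometres.
#' @return A tibble of class `grid_template` with columns `id, u, v`.
#' @export
build_grid <- function(n_rows, n_cols, bbox) {
  if (n_rows < 2 || n_cols < 2) abort("grid needs at least 2 rows and 2 cols")
  bbox <- as.numeric(bbox)
  if (length(bbox) != 4 || bbox[2] <= bbox[1] || bbox[4] <= bbox[3])
    abort("degenerate bbox: need umax > umin and vmax > vmin")
  u <- seq(bbox[1], bbox[2], length.out = n_cols)
  v <- seq(bbox[3], bbox[4], length.out = n_rows)
  out <- tibble(id = 0:(n_rows * n_cols - 1L),
                u = rep(u, times = n_rows),
                v = rep(v, each = n_cols))
  attr(out, "n_rows") <- as.integer(n_rows)
  attr(out, "n_cols") <- as.integer(n_cols)
  class(out) <- c("grid_template", class(out))
  out
}

grid_dims <- function(grid) {
  c(attr(grid, "n_rows") %||% NA_integer_, attr(grid, "n_cols") %||% NA_integer_)
}

as_grid_df <- function(grid) {
  if (!is.data.frame(grid) || !all(c("id", "u", "v") %in% names(grid)))
    abort("grid must have columns id, u, v")
  grid
}

keep_grid_attrs <- function(new_uv, grid) {
  out <- tibble(id = grid$id, u = new_uv[, 1], v = new_uv[, 2])
  attr(out, "n_rows") <- attr(grid, "n_rows")
  attr(out, "n_cols") <- attr(grid, "n_cols")
  class(out) <- c("grid_template", class(out))
  out
}

#' Thin-plate-spline warp of a template grid onto specimen landmarks
#'
#' Fits the 2D thin-plate spline interpolant that carries the template
#' landmark positions onto the specimen landmark positions (exactly, when
#' `lambda = 0`) and applies it to every grid point, preserving ids. This is
#' the programmatic stand-in for interactive grid adjustment: a smooth,
#' "elastic" deformation anchored at a handful of recurring outline
#' features.
#'
#' @param grid a `grid_template` (or any tibble with `id, u, v`).
#' @param landmark_pairs data frame with columns
#'   `u_template, v_template, u_specimen, v_specimen`; at least 3
#'   non-collinear template points.
#' @param lambda non-negative TPS regularisation (0 = exact interpolation).
#' @return The warped `grid_template`.
#' @export
tps_warp <- function(grid, landmark_pairs, lambda = 0) {
  grid <- as_grid_df(grid)
  lp <- landmark_pairs
  need <- c("u_template", "v_template", "u_specimen", "v_specimen")
  if (!all(need %in% names(lp))) abort("landmark_pairs lacks required columns")
  src <- cbind(lp$u_template, lp$v_template)
  dst <- cbind(lp$u_specimen, lp$v_specimen)
  if (nrow(src) < 3) abort("need at least 3 landmark pairs")
  if (lambda < 0) abort("lambda must be >= 0")
  fit <- tps_fit(src, dst, lambda)
  keep_grid_attrs(tps_apply(fit, cbind(grid$u, grid$v)), grid)
}

tps_kernel <- function(r2) ifelse(r2 == 0, 0, 0.5 * r2 * log(r2))

# the system is solved in centred, unit-scaled coordinates for conditioning
tps_fit <- function(src, dst, lambda = 0) {
  n <- nrow(src)
  mu <- colMeans(src)
  sc <- mean(sqrt(rowSums(sweep(src, 2, mu)^2)))
  if (!is.finite(sc) || sc <= 0)
    abort("singular TPS system: landmarks are collinear or duplicated")
  srcn <- sweep(src, 2, mu) / sc
  dstn <- sweep(dst, 2, mu) / sc
  d2 <- as.matrix(stats::dist(srcn))^2
  K <- tps_kernel(d2) + diag(lambda, n)
  P <- cbind(1, srcn)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(dstn, matrix(0, 3, 2))
  coef <- tryCatch(solve(L, rhs), error = function(e)
    abort("singular TPS system: landmarks are collinear or duplicated"))
  if (any(!is.finite(coef)))
    abort("singular TPS system: landmarks are collinear or duplicated")
  list(src = srcn, mu = mu, sc = sc,
       w = coef[seq_len(n), , drop = FALSE],
       a = coef[n + 1:3, , drop = FALSE])
}

tps_apply <- function(fit, pts) {
  ptsn <- sweep(pts, 2, fit$mu) / fit$sc
  d2 <- outer(rowSums(ptsn^2), rowSums(fit$src^2), "+") -
    2 * ptsn %*% t(fit$src)
  d2[d2 < 0] <- 0
  outn <- cbind(1, ptsn) %*% fit$a + tps_kernel(d2) %*% fit$w
  sweep(outn * fit$sc, 2, fit$mu, `+`)
}

#' Bind a grid to a deformation cage / deform by moving the cage
#'
#' `cage_bind` computes, for every grid point, its 2D mean-value coordinates
#' with respect to the vertices of a closed polygonal cage that encloses the
#' grid. `cage_deform` then maps the grid through any displaced copy of the
#' cage: new positions are simply the weight matrix times the moved cage
#' vertices. An unchanged cage reproduces the grid exactly (partition of
#' unity + linear precision), and affine motions of the cage move the grid
#' affinely.
#'
#' @param grid a `grid_template`.
#' @param cage_polygon numeric matrix (k x 2) of cage vertices in order,
#'   closed implicitly; all grid points must lie strictly inside.
#' @return `cage_bind`: an object of class `deform_cage` holding the cage
#'   and the weight matrix. `cage_deform`: the deformed `grid_template`.
#' @export
cage_bind <- function(grid, cage_polygon) {
  grid <- as_grid_df(grid)
  cage <- as.matrix(cage_polygon)
  if (ncol(cage) != 2 || nrow(cage) < 3) abort("cage must be a k x 2 polygon, k >= 3")
  if (polygon_self_intersects(cage)) abort("self-intersecting cage polygon")
  W <- mean_value_coords(cbind(grid$u, grid$v), cage)
  structure(list(grid = grid, cage = cage, weights = W), class = "deform_cage")
}

#' @rdname cage_bind
#' @param binding a `deform_cage` from `cage_bind`.
#' @param moved_cage the cage polygon after editing (same vertex count/order).
#' @export
cage_deform <- function(binding, moved_cage) {
  stopifnot(inherits(binding, "deform_cage"))
  moved <- as.matrix(moved_cage)
  if (!all(dim(moved) == dim(binding$cage)))
    abort("moved_cage must match the bound cage's vertex count")
  keep_grid_attrs(binding$weights %*% moved, binding$grid)
}

# Floater mean-value coordinates of points strictly inside a closed polygon
mean_value_coords <- function(pts, cage) {
  k <- nrow(cage)
  n <- nrow(pts)
  sx <- outer(pts[, 1], cage[, 1], function(p, v) v - p)
  sy <- outer(pts[, 2], cage[, 2], function(p, v) v - p)
  r <- sqrt(sx^2 + sy^2)
  if (any(r < 1e-12)) abort("grid point coincides with a cage vertex")
  nxt <- c(2:k, 1)
  cross <- sx * sy[, nxt] - sy * sx[, nxt]
  dot <- sx * sx[, nxt] + sy * sy[, nxt]
  # winding check: points must be strictly inside the cage
  ang <- atan2(cross, dot)
  wind <- abs(rowSums(ang))
  if (any(wind < pi)) abort("grid point outside the cage polygon")
  if (any(abs(cross) < 1e-12 & dot < 0))
    abort("grid point lies on a cage edge")
  thalf <- cross / (r * r[, nxt] + dot)
  prv <- c(k, 1:(k - 1))
  w <- (thalf[, prv] + thalf) / r
  w / rowSums(w)
}

polygon_self_intersects <- function(cage) {
  k <- nrow(cage)
  seg <- cbind(cage, cage[c(2:k, 1), ])
  inter <- function(a, b) {
    d1 <- orient2(b[1:2], b[3:4], a[1:2]); d2 <- orient2(b[1:2], b[3:4], a[3:4])
    d3 <- orient2(a[1:2], a[3:4], b[1:2]); d4 <- orient2(a[1:2], a[3:4], b[3:4])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(k - 2)) {
    for (j in seq(i + 2, k)) {
      if (i == 1 && j == k) next # adjacent through closure
      if (inter(seg[i, ], seg[j, ])) return(TRUE)
    }
  }
  FALSE
}

orient2 <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])

#' Project a grid onto a surface mesh ("shrink-wrap")
#'
#' For each grid point `(u, v)` a ray `x = u, y = v` parallel to the z axis
#' is intersected with every overlapping mesh triangle. Points with at
#' least one hit become cast points `(u, v, z*)` where `z*` is the
#' maximum-z intersection, i.e. the outermost surface toward the viewer
#' (the scanned near side). Points whose ray misses the mesh silhouette are
#' marked invalid and excluded from all downstream analysis.
#'
#' @param grid a `grid_template` (possibly warped), same (x, y) frame as
#'   the mesh.
#' @param mesh a [triangle_mesh()].
#' @return A cast ([new_cast()]) with `x, y` equal to the grid coordinates
#'   exactly.
#' @export
shrink_wrap <- function(grid, mesh) {
  grid <- as_grid_df(grid)
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$faces) == 0) abort("empty mesh")
  pu <- grid$u; pv <- grid$v
  V <- mesh$vertices; f <- mesh$faces
  x1 <- V[f[, 1], 1]; y1 <- V[f[, 1], 2]; z1 <- V[f[, 1], 3]
  x2 <- V[f[, 2], 1]; y2 <- V[f[, 2], 2]; z2 <- V[f[, 2], 3]
  x3 <- V[f[, 3], 1]; y3 <- V[f[, 3], 2]; z3 <- V[f[, 3], 3]
  # bin grid points into square cells sized to the median triangle extent
  ext <- pmax(pmax(x1, x2, x3) - pmin(x1, x2, x3),
              pmax(y1, y2, y3) - pmin(y1, y2, y3))
  cs <- max(stats::median(ext), 1e-6)
  ox <- min(pu) - cs; oy <- min(pv) - cs
  ncx <- max(1L, ceiling((max(pu) - ox) / cs) + 1L)
  ncy <- max(1L, ceiling((max(pv) - oy) / cs) + 1L)
  cellx <- pmin(pmax(floor((pu - ox) / cs), 0), ncx - 1)
  celly <- pmin(pmax(floor((pv - oy) / cs), 0), ncy - 1)
  cell_of <- as.integer(cellx + ncx * celly + 1)
  buckets <- split(seq_along(pu), cell_of)
  zbest <- rep(-Inf, length(pu))
  tol <- 1e-9
  for (t in seq_len(nrow(f))) {
    cx0 <- max(0, floor((min(x1[t], x2[t], x3[t]) - ox) / cs))
    cx1 <- min(ncx - 1, floor((max(x1[t], x2[t], x3[t]) - ox) / cs))
    cy0 <- max(0, floor((min(y1[t], y2[t], y3[t]) - oy) / cs))
    cy1 <- min(ncy - 1, floor((max(y1[t], y2[t], y3[t]) - oy) / cs))
    if (cx1 < cx0 || cy1 < cy0) next
    keys <- as.character(as.integer(outer(cx0:cx1, ncx * (cy0:cy1), "+") + 1))
    cand <- unlist(buckets[keys], use.names = FALSE)
    if (length(cand) == 0) next
    den <- (y2[t] - y3[t]) * (x1[t] - x3[t]) + (x3[t] - x2[t]) * (y1[t] - y3[t])
    if (abs(den) < 1e-14) next
    l1 <- ((y2[t] - y3[t]) * (pu[cand] - x3[t]) +
             (x3[t] - x2[t]) * (pv[cand] - y3[t])) / den
    l2 <- ((y3[t] - y1[t]) * (pu[cand] - x3[t]) +
             (x1[t] - x3[t]) * (pv[cand] - y3[t])) / den
    l3 <- 1 - l1 - l2
    hit <- l1 >= -tol & l2 >= -tol & l3 >= -tol
    if (!any(hit)) next
    zq <- l1[hit] * z1[t] + l2[hit] * z2[t] + l3[hit] * z3[t]
    ci <- cand[hit]
    upd <- zq > zbest[ci]
    zbest[ci[upd]] <- zq[upd]
  }
  valid <- is.finite(zbest)
  dims <- grid_dims(grid)
  new_cast(grid$id, pu, pv, ifelse(valid, zbest, NA_real_), valid,
           n_rows = dims[1], n_cols = dims[2])
}

#' Wrap one specimen: warp the template, then shrink-wrap
#'
#' Composes [tps_warp()] (when `landmark_pairs` is given) or [cage_deform()]
#' (when `binding` + `moved_cage` are given) with [shrink_wrap()]. With
#' neither, the template is projected unwarped. Fully deterministic.
#'
#' @param mesh a [triangle_mesh()].
#' @param template a `grid_template`.
#' @param landmark_pairs optional landmark pair table for TPS warping.
#' @param binding,moved_cage optional cage binding and edited cage.
#' @param lambda TPS regularisation.
#' @return A cast.
#' @export
wrap_specimen <- function(mesh, template, landmark_pairs = NULL,
                          binding = NULL, moved_cage = NULL, lambda = 0) {
  grid <- template
  if (!is.null(landmark_pairs)) {
    grid <- tps_warp(grid, landmark_pairs, lambda)
  } else if (!is.null(binding)) {
    if (is.null(moved_cage)) abort("moved_cage required with a cage binding")
    grid <- cage_deform(binding, moved_cage)
  }
  shrink_wrap(grid, mesh)
}
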