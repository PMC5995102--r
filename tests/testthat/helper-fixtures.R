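# fixtures are built in code: geometry, oracles and tiny casts

# rotation matrix from axis + angle (Rodrigues)
rotation_about <- function(axis, angle) {
  ax <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# lat-long triangulated hemisphere of radius R, dome toward +z
hemisphere_mesh <- function(R = 100, n_theta = 60, n_phi = 120) {
  th <- seq(0, pi / 2, length.out = n_theta)
  ph <- seq(0, 2 * pi, length.out = n_phi)
  gg <- expand.grid(th = th, ph = ph)
  verts <- cbind(R * sin(gg$th) * cos(gg$ph), R * sin(gg$th) * sin(gg$ph),
                 R * cos(gg$th))
  idx <- function(i, j) (j - 1) * n_theta + i
  f <- vector("list", n_phi - 1)
  for (j in seq_len(n_phi - 1)) {
    i <- seq_len(n_theta - 1)
    f[[j]] <- rbind(cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
                    cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  }
  triangle_mesh(verts, do.call(rbind, f))
}

# two-triangle plane z = level covering [-s, s]^2
plane_mesh <- function(level = 0, s = 1000) {
  triangle_mesh(rbind(c(-s, -s, level), c(s, -s, level), c(s, s, level),
                      c(-s, s, level)),
                rbind(c(1, 2, 3), c(1, 3, 4)))
}

random_cast <- function(n = 50, seed = NULL, scale = 100) {
  if (!is.null(seed)) set.seed(seed)
  new_cast(0:(n - 1), rnorm(n) * scale, rnorm(n) * scale, rnorm(n) * scale)
}

rigid_copy <- function(cast, R, tvec) {
  m <- as.matrix(cast[, c("x", "y", "z")]) %*% t(R) +
    matrix(tvec, nrow(cast), 3, byrow = TRUE)
  new_cast(cast$id, m[, 1], m[, 2], m[, 3], cast$valid)
}

# binary ball volume at 1 um spacing, centred, with margin (voxels)
ball_volume <- function(r = 50, spacing = 1, margin = 10) {
  n <- 2 * ceiling(r / spacing) + 2 * margin + 1
  ax <- (seq_len(n) - (n + 1) / 2) * spacing
  gg <- expand.grid(z = ax, y = ax, x = ax)
  intensity_volume(array(as.numeric(gg$x^2 + gg$y^2 + gg$z^2 <= r^2),
                         c(n, n, n)),
                   c(spacing, spacing, spacing))
}

# brute-force two-sided rank-sum p by complete enumeration of rank splits
ranksum_enumerate <- function(a, b) {
  vals <- c(a, b)
  N <- length(vals)
  r <- rank(vals)
  W_obs <- sum(r[seq_along(a)])
  splits <- utils::combn(N, length(a))
  Ws <- apply(splits, 2, function(ix) sum(r[ix]))
  min(2 * min(mean(Ws <= W_obs), mean(Ws >= W_obs)), 1)
}

# independent overlap oracle: dense sampling of E1 (interior + boundary)
# refined by Nelder-Mead on a ball parameterisation; no Lagrange step
oracle_ellipsoid_overlap <- function(c1, r1, c2, r2, n = 3000) {
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- rbind(sweep(u * runif(n)^(1 / 3), 2, r1, `*`),
               sweep(u, 2, r1, `*`))
  pts <- sweep(pts, 2, c1, `+`)
  q2 <- rowSums(sweep(sweep(pts, 2, c2), 2, r2, `/`)^2)
  f <- function(w) {
    nw <- sqrt(sum(w^2))
    x <- c1 + r1 * (if (nw > 1) w / nw else w)
    sum(((x - c2) / r2)^2)
  }
  w0 <- (pts[which.min(q2), ] - c1) / r1
  res <- stats::optim(w0, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000))
  min(res$value, min(q2)) <= 1 + 1e-9
}

# small synthetic study configuration used by pipeline tests
small_sim_config <- function(seed = 1, n_control = 4, n_treated = 4,
                             rows = 60, cols = 48) {
  study_config(
    grid_rows = rows, grid_cols = cols, seed = seed,
    n_permutations = 2,
    simulate = list(n_control = n_control, n_treated = n_treated,
                    individual_noise_sd = 4,
                    grid_bbox = c(-860, 860, -1960, 1260)))
}
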