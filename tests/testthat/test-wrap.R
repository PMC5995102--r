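test_that("grid templates are row-major, complete and validated", {
  g <- build_grid(2, 2, c(0, 1, 0, 1))
  expect_equal(g$id, 0:3)
  expect_equal(g$u, c(0, 1, 0, 1))
  expect_equal(g$v, c(0, 0, 1, 1))

  big <- build_grid(400, 320, c(0, 1, 0, 1))
  expect_equal(nrow(big), 128000)
  expect_false(anyDuplicated(big$id) > 0)

  expect_error(build_grid(2, 2, c(1, 1, 0, 1)), "degenerate")
  expect_error(build_grid(1, 5, c(0, 1, 0, 1)), "at least 2")
})

test_that("TPS warping is exact on identity, shifts and affine maps", {
  g <- build_grid(15, 12, c(-50, 50, -80, 80))
  lm <- tibble::tibble(u_template = c(-40, 35, 0, -10, 22),
                       v_template = c(-70, -55, 60, 10, -20))
  same <- dplyr::mutate(lm, u_specimen = u_template, v_specimen = v_template)
  w0 <- tps_warp(g, same)
  expect_equal(w0$u, g$u, tolerance = 1e-9)
  expect_equal(w0$v, g$v, tolerance = 1e-9)

  shift <- dplyr::mutate(lm, u_specimen = u_template + 7.5,
                         v_specimen = v_template - 3.25)
  w1 <- tps_warp(g, shift)
  expect_equal(w1$u, g$u + 7.5, tolerance = 1e-8)
  expect_equal(w1$v, g$v - 3.25, tolerance = 1e-8)

  A <- matrix(c(1.3, 0.2, -0.1, 0.9), 2, 2); b <- c(5, -2)
  dst <- as.matrix(lm) %*% t(A) + matrix(b, 5, 2, byrow = TRUE)
  aff <- dplyr::mutate(lm, u_specimen = dst[, 1], v_specimen = dst[, 2])
  w2 <- tps_warp(g, aff)
  exp_uv <- cbind(g$u, g$v) %*% t(A) + matrix(b, nrow(g), 2, byrow = TRUE)
  expect_equal(w2$u, exp_uv[, 1], tolerance = 1e-6)
  expect_equal(w2$v, exp_uv[, 2], tolerance = 1e-6)

  coll <- tibble::tibble(u_template = c(0, 1, 2), v_template = c(0, 1, 2),
                         u_specimen = c(0, 1, 2.5), v_specimen = c(0, 1, 2))
  expect_error(tps_warp(g, coll), "singular")
})

test_that("cage binding has linear precision and partition of unity", {
  g <- build_grid(10, 10, c(-1, 1, -1, 1))
  cage <- rbind(c(-2, -2), c(2, -2), c(2.5, 0), c(2, 2), c(-2, 2.2),
                c(-2.4, 0))
  bind <- cage_bind(g, cage)
  expect_equal(rowSums(bind$weights), rep(1, nrow(g)), tolerance = 1e-12)

  same <- cage_deform(bind, cage)
  expect_equal(same$u, g$u, tolerance = 1e-9)
  expect_equal(same$v, g$v, tolerance = 1e-9)

  moved <- sweep(cage, 2, c(3, -4), `+`)
  tr <- cage_deform(bind, moved)
  expect_equal(tr$u, g$u + 3, tolerance = 1e-9)
  expect_equal(tr$v, g$v - 4, tolerance = 1e-9)

  sq <- rbind(c(-2, -2), c(2, -2), c(2, 2), c(-2, 2))
  bsq <- cage_bind(g, sq)
  stretched <- sq %*% diag(c(2, 1))
  st <- cage_deform(bsq, stretched)
  expect_equal(st$u, 2 * g$u, tolerance = 1e-6)
  expect_equal(st$v, g$v, tolerance = 1e-6)

  outside <- build_grid(3, 3, c(-5, 5, -5, 5))
  expect_error(cage_bind(outside, sq), "outside")
  bowtie <- rbind(c(-2, -2), c(2, 2), c(2, -2), c(-2, 2))
  expect_error(cage_bind(g, bowtie), "self-intersecting")
})

test_that("cage and TPS paths agree when both encode the same affine map", {
  g <- build_grid(12, 12, c(-1, 1, -1, 1))
  sq <- rbind(c(-3, -3), c(3, -3), c(3, 3), c(-3, 3))
  A <- matrix(c(1.4, 0.3, -0.2, 1.1), 2, 2); b <- c(0.5, -1)
  moved <- sq %*% t(A) + matrix(b, 4, 2, byrow = TRUE)
  via_cage <- cage_deform(cage_bind(g, sq), moved)
  lm <- tibble::tibble(u_template = sq[, 1], v_template = sq[, 2],
                       u_specimen = moved[, 1], v_specimen = moved[, 2])
  via_tps <- tps_warp(g, lm)
  expect_equal(via_cage$u, via_tps$u, tolerance = 1e-6)
  expect_equal(via_cage$v, via_tps$v, tolerance = 1e-6)
})

test_that("shrink-wrap projects exactly onto planes and hemispheres", {
  g <- build_grid(12, 12, c(-40, 40, -40, 40))
  flat <- shrink_wrap(g, plane_mesh(12.5, 100))
  expect_true(all(flat$valid))
  expect_equal(flat$z, rep(12.5, nrow(g)), tolerance = 1e-12)
  expect_identical(flat$x, g$u)
  expect_identical(flat$y, g$v)

  R <- 100
  hemi <- hemisphere_mesh(R)
  gh <- build_grid(25, 25, c(-60, 60, -60, 60))
  cast <- shrink_wrap(gh, hemi)
  inside <- sqrt(gh$u^2 + gh$v^2) < 0.8 * R
  expect_true(all(cast$valid[inside]))
  edge_len <- R * (pi / 2) / 59
  err <- abs(cast$z[inside] - sqrt(R^2 - gh$u[inside]^2 - gh$v[inside]^2))
  expect_lt(max(err), edge_len)

  far <- build_grid(3, 3, c(200, 300, 200, 300))
  miss <- shrink_wrap(far, hemi)
  expect_false(any(miss$valid))
  expect_error(shrink_wrap(g, triangle_mesh(matrix(0, 1, 3),
                                            matrix(integer(0), 0, 3))),
               "empty mesh")
})

test_that("growing the silhouette never invalidates a valid point", {
  g <- build_grid(20, 20, c(-80, 80, -80, 80))
  small <- shrink_wrap(g, hemisphere_mesh(60, 40, 80))
  large <- shrink_wrap(g, hemisphere_mesh(95, 40, 80))
  expect_true(all(large$valid[small$valid]))
})

test_that("wrap_specimen composes warp + projection deterministically", {
  body <- make_half_body(body_params(), mesh_step = 60)
  g <- build_grid(40, 32, c(-860, 860, -1960, 1260))
  lm <- body$landmarks
  pairs <- tibble::tibble(u_template = lm$u, v_template = lm$v,
                          u_specimen = lm$u, v_specimen = lm$v)
  c1 <- wrap_specimen(body$mesh, g, landmark_pairs = pairs)
  c2 <- wrap_specimen(body$mesh, g, landmark_pairs = pairs)
  expect_identical(c1, c2)
  # silhouette coverage: most grid points over the body project
  frame <- abs(g$u) < 700 & g$v > -1100 & g$v < 1100
  expect_gt(mean(c1$valid[frame]), 0.9)
  # projected x, y equal the (identity-)warped grid coordinates
  expect_equal(c1$x, g$u, tolerance = 1e-9)
  expect_equal(c1$y, g$v, tolerance = 1e-9)
})
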