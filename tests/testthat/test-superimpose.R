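test_that("identity and known rigid motions are recovered exactly", {
  ref <- random_cast(80, seed = 5)
  fit0 <- procrustes(ref, ref)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(fit0$scale, 1)
  expect_lt(fit0$distance, 1e-18)

  R <- rotation_about(c(1, 2, 3), 0.8)
  tv <- c(40, -15, 60)
  mov <- rigid_copy(ref, R, tv)
  fit <- procrustes(ref, mov)
  size <- sum(scale(as.matrix(ref[, c("x", "y", "z")]), scale = FALSE)^2)
  expect_lt(fit$distance / size, 1e-12)
  # moving = ref %*% t(R): the fit applies R on the right to undo it
  expect_equal(fit$rotation, R, tolerance = 1e-9)
  expect_equal(crossprod(fit$rotation), diag(3), tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  al <- fit$aligned
  expect_equal(al$x, ref$x, tolerance = 1e-9)
  expect_equal(al$z, ref$z, tolerance = 1e-9)
})

test_that("pure size differences: partial fit keeps size, full removes it", {
  ref <- random_cast(60, seed = 6)
  dbl <- new_cast(ref$id, 2 * ref$x, 2 * ref$y, 2 * ref$z)
  fitP <- procrustes(ref, dbl, allow_scaling = FALSE)
  expect_equal(fitP$scale, 1)
  expect_gt(fitP$distance, 0)
  # centroid size of the moving configuration is preserved without scaling
  csize <- function(df) sqrt(sum(scale(as.matrix(df[, c("x", "y", "z")]),
                                       scale = FALSE)^2))
  expect_equal(csize(fitP$aligned), csize(dbl), tolerance = 1e-9)

  fitF <- procrustes(ref, dbl, allow_scaling = TRUE)
  expect_equal(fitF$scale, 0.5, tolerance = 1e-12)
  size <- sum(scale(as.matrix(ref[, c("x", "y", "z")]), scale = FALSE)^2)
  expect_lt(fitF$distance / size, 1e-12)
})

test_that("distance is invariant to rigid pre-motion of the moving cast", {
  ref <- random_cast(50, seed = 7)
  mov <- random_cast(50, seed = 8)
  d0 <- procrustes(ref, mov)$distance
  for (i in 1:4) {
    pre <- rigid_copy(mov, rotation_about(rnorm(3), runif(1, 0, pi)),
                      rnorm(3, 0, 50))
    expect_equal(procrustes(ref, pre)$distance, d0, tolerance = 1e-6)
  }
})

test_that("fit uses the valid-id intersection, then transforms all points", {
  ref <- random_cast(40, seed = 9)
  mov <- rigid_copy(ref, rotation_about(c(0, 0, 1), 0.3), c(5, 5, 5))
  ref$valid[1:5] <- FALSE
  mov$valid[36:40] <- FALSE
  fit <- procrustes(ref, mov)
  expect_equal(fit$n_common, 30)
  al <- fit$aligned
  # points invalid in the reference but valid in moving are still mapped
  expect_true(all(al$valid == mov$valid))
  expect_equal(al$x[al$valid], ref$x[mov$valid], tolerance = 1e-9)

  mov2 <- mov; mov2$valid[] <- FALSE; mov2$valid[1:2] <- TRUE
  expect_error(procrustes(ref, mov2), "fewer than 3")
})

test_that("degenerate configurations are rejected", {
  line <- new_cast(0:9, 1:10, 2 * (1:10), 3 * (1:10))
  expect_error(procrustes(line, line), "collinear|zero-variance")
  zero <- new_cast(0:9, rep(1, 10), rep(2, 10), rep(3, 10))
  expect_error(procrustes(zero, zero), "zero-variance")
})

test_that("independent route: vegan recovers the same superimposition", {
  skip_if_not_installed("vegan")
  ref <- random_cast(30, seed = 10)
  mov <- rigid_copy(ref, rotation_about(c(2, -1, 1), 0.5), c(10, 0, -5))
  set.seed(12)
  mov$x <- mov$x + rnorm(30, 0, 2)
  mov$y <- mov$y + rnorm(30, 0, 2)
  mov$z <- mov$z + rnorm(30, 0, 2)
  ours <- procrustes(ref, mov, allow_scaling = TRUE)
  vg <- vegan::procrustes(as.matrix(ref[, c("x", "y", "z")]),
                          as.matrix(mov[, c("x", "y", "z")]),
                          scale = TRUE, symmetric = FALSE)
  expect_equal(ours$distance, vg$ss, tolerance = 1e-8)
  expect_equal(ours$rotation, vg$rotation, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(ours$scale, vg$scale, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("star alignment recovers a common shape and keeps the prototype", {
  base <- random_cast(45, seed = 13)
  set.seed(14)
  casts <- c(list(base), lapply(1:5, function(i)
    rigid_copy(base, rotation_about(rnorm(3), runif(1, 0, pi)),
               rnorm(3, 0, 100))))
  al <- align_group(casts, prototype = 1)
  expect_identical(al[[1]], base)
  for (i in 2:6) {
    rmsd <- sqrt(mean((al[[i]]$x - base$x)^2 + (al[[i]]$y - base$y)^2 +
                        (al[[i]]$z - base$z)^2))
    expect_lt(rmsd, 1e-9)
  }
  two <- base; two$valid[] <- FALSE; two$valid[1:2] <- TRUE
  expect_error(align_group(c(casts, list(two)), prototype = 1),
               "fewer than 3")
})

test_that("tidy/glance expose the fit as tibbles", {
  ref <- random_cast(20, seed = 15)
  mov <- rigid_copy(ref, rotation_about(c(1, 0, 0), 0.2), c(1, 2, 3))
  fit <- procrustes(ref, mov)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 20)
  gl <- glance(fit)
  expect_equal(gl$n_common, 20)
  expect_lt(gl$rmsd, 1e-9)
})
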