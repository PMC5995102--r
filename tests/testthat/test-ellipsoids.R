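test_that("confidence radii follow the t-based CI of the mean", {
  base <- random_cast(20, seed = 30)
  same <- confidence_ellipsoids(list(base, base, base))
  expect_true(all(same$rx == 0 & same$ry == 0 & same$rz == 0))
  expect_equal(same$x, base$x)

  set.seed(31)
  group <- lapply(1:9, function(i) {
    c_ <- base
    c_$x <- c_$x + rnorm(20, 0, 3)
    c_
  })
  es <- confidence_ellipsoids(group, ci_level = 0.95)
  xs <- sapply(group, function(c_) c_$x)
  sref <- apply(xs, 1, sd)
  expect_equal(es$rx, qt(0.975, 8) * sref / 3, tolerance = 1e-12)
  expect_equal(qt(0.975, 8), 2.306, tolerance = 1e-3)
  expect_equal(es$n, rep(9L, 20), ignore_attr = TRUE)

  zero <- confidence_ellipsoids(group, ci_level = 0)
  expect_true(all(zero$rx == 0))
  obs <- confidence_ellipsoids(group, ci_kind = "observation")
  expect_equal(obs$rx, qt(0.975, 8) * sref * sqrt(1 + 1 / 9),
               tolerance = 1e-12)
  expect_error(confidence_ellipsoids(group[1]), "at least 2")
})

test_that("ellipsoid overlap handles identity, tangency and separation", {
  expect_true(ellipsoid_overlap(c(1, 2, 3), c(2, 1, 0.5),
                                c(1, 2, 3), c(2, 1, 0.5)))
  expect_true(ellipsoid_overlap(c(0, 0, 0), c(1, 1, 1), c(2, 0, 0),
                                c(1, 1, 1))) # tangent counts as overlap
  expect_false(ellipsoid_overlap(c(0, 0, 0), c(1, 1, 1), c(3, 0, 0),
                                 c(1, 1, 1)))
  expect_error(ellipsoid_overlap(c(0, 0, 0), c(-1, 1, 1), c(1, 0, 0),
                                 c(1, 1, 1)), "negative")
})

test_that("degenerate radii reduce to point membership", {
  # two distinct points never overlap; identical points do
  expect_false(ellipsoid_overlap(c(0, 0, 0), c(0, 0, 0), c(1e-6, 0, 0),
                                 c(0, 0, 0)))
  expect_true(ellipsoid_overlap(c(1, 1, 1), c(0, 0, 0), c(1, 1, 1),
                                c(0, 0, 0)))
  # a point against an ellipsoid: inside iff its quadratic form <= 1
  expect_true(ellipsoid_overlap(c(0, 0, 0), c(2, 2, 2), c(1, 1, 1),
                                c(0, 0, 0)))
  expect_false(ellipsoid_overlap(c(0, 0, 0), c(0.5, 0.5, 0.5), c(1, 1, 1),
                                 c(0, 0, 0)))
  # flat disc against a sphere: touching plane
  expect_true(ellipsoid_overlap(c(0, 0, 0), c(1, 1, 0), c(0, 0, 1),
                                c(1, 1, 1)))
  expect_false(ellipsoid_overlap(c(0, 0, 0), c(1, 1, 0), c(0, 0, 1.5),
                                 c(1, 1, 1)))
})

test_that("verdicts agree with the sampling oracle on random pairs", {
  set.seed(32)
  n_checked <- 0
  for (i in 1:500) {
    c1 <- runif(3, -3, 3); c2 <- runif(3, -3, 3)
    r1 <- runif(3, 0.2, 2); r2 <- runif(3, 0.2, 2)
    got <- ellipsoid_overlap(c1, r1, c2, r2)
    # symmetry on every case
    expect_identical(got, ellipsoid_overlap(c2, r2, c1, r1))
    # radius monotonicity: growing radii never destroys overlap
    if (got) expect_true(ellipsoid_overlap(c1, r1 * 1.5, c2, r2 * 1.2))
    ora <- oracle_ellipsoid_overlap(c1, r1, c2, r2)
    expect_identical(got, ora)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 500)
})

test_that("constructed tangent pairs are classified as overlapping", {
  set.seed(33)
  for (i in 1:20) {
    r1 <- runif(3, 0.3, 2); r2 <- runif(3, 0.3, 2)
    dir <- c(1, 0, 0)
    c2 <- c(r1[1] + r2[1], 0, 0) # touching along the x axis
    expect_true(ellipsoid_overlap(c(0, 0, 0), r1, c2, r2))
    expect_false(ellipsoid_overlap(c(0, 0, 0), r1, c2 + c(1e-6, 0, 0), r2))
  }
})

test_that("overlap maps colour purple/black and use shared ids", {
  base <- random_cast(25, seed = 34)
  set.seed(35)
  grp <- lapply(1:6, function(i) {
    c_ <- base
    c_$x <- c_$x + rnorm(25); c_$y <- c_$y + rnorm(25)
    c_$z <- c_$z + rnorm(25)
    c_
  })
  ea <- confidence_ellipsoids(grp[1:3])
  om_same <- overlap_map(ea, ea)
  expect_true(all(om_same$overlap))
  expect_true(all(om_same$colour == "purple"))

  eb <- ea
  eb$x <- eb$x + (max(ea$rx) + max(eb$rx) + 1) * 2
  om_far <- overlap_map(ea, eb)
  expect_true(all(!om_far$overlap))
  expect_true(all(om_far$colour == "black"))

  eb2 <- confidence_ellipsoids(grp[4:6])
  eb2 <- eb2[eb2$id %in% 0:19, ]
  om <- overlap_map(ea, eb2)
  expect_equal(sort(om$id), 0:19)
})

test_that("permutation swaps preserve group sizes and are seeded", {
  base <- random_cast(20, seed = 36)
  set.seed(37)
  casts <- lapply(1:19, function(i) {
    c_ <- base
    c_$z <- c_$z + rnorm(20)
    c_
  })
  labels <- rep(c("undefended", "defended"), c(10, 9))
  p1 <- permute_and_test(casts, labels, fraction = 0.5, n_permutations = 3,
                         seed = 99)
  p2 <- permute_and_test(casts, labels, fraction = 0.5, n_permutations = 3,
                         seed = 99)
  expect_identical(lapply(p1, as.data.frame), lapply(p2, as.data.frame))
  sw <- attr(p1[[1]], "swapped")
  expect_length(sw$from_a, 4) # floor(0.5 * 9)
  expect_length(sw$from_b, 4)
  expect_error(permute_and_test(casts, labels, fraction = 0.05),
               "zero casts")
  expect_error(permute_and_test(casts, rep("a", 19)), "two groups")
})
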