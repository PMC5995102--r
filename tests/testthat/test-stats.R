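test_that("mean models average members and intersect validity", {
  a <- random_cast(30, seed = 20)
  expect_equal(mean_model(list(a))$x, a$x)

  up <- a; up$z <- a$z + 4
  dn <- a; dn$z <- a$z - 4
  m <- mean_model(list(up, dn))
  expect_equal(m$z, a$z, tolerance = 1e-12)
  expect_equal(unique(m$n_used[m$valid]), 2L)

  dn$valid[7] <- FALSE # id 6
  m2 <- mean_model(list(up, dn, a, a, a))
  expect_false(m2$valid[7])
  expect_true(all(m2$valid[-7]))
  expect_error(mean_model(list()), "empty group")
})

test_that("mean_model commutes with a rigid motion of all members", {
  set.seed(21)
  casts <- lapply(1:4, function(i) random_cast(25))
  R <- rotation_about(c(1, 1, 0), 0.6); tv <- c(3, -2, 9)
  m1 <- mean_model(lapply(casts, rigid_copy, R = R, tvec = tv))
  m0 <- rigid_copy(mean_model(casts), R, tv)
  expect_equal(m1$x, m0$x, tolerance = 1e-9)
  expect_equal(m1$y, m0$y, tolerance = 1e-9)
  expect_equal(m1$z, m0$z, tolerance = 1e-9)
})

test_that("displacement fields obey the pythagorean magnitude", {
  a <- random_cast(40, seed = 22)
  d0 <- displacement_field(a, a)
  expect_true(all(d0$magnitude < 1e-9))

  expect_equal(displacement_field(a, a)$id, a$id)
  # a pure per-id offset after alignment is impossible to construct exactly
  # (procrustes removes part of it), so verify the magnitude invariant
  b <- a
  set.seed(23)
  b$x <- b$x + rnorm(40); b$y <- b$y + rnorm(40); b$z <- b$z + rnorm(40)
  d <- displacement_field(a, b)
  expect_equal(d$magnitude^2, d$dx^2 + d$dy^2 + d$dz^2, tolerance = 1e-9)

  big <- new_cast(a$id, 1.1 * a$x, 1.1 * a$y, 1.1 * a$z)
  dF <- displacement_field(a, big, allow_scaling = TRUE)
  expect_lt(max(dF$magnitude), 1e-9)
  dP <- displacement_field(a, big, allow_scaling = FALSE)
  expect_gt(median(dP$magnitude), 1)
})

test_that("rank-sum fields match wilcox.test and the enumeration oracle", {
  set.seed(24)
  M <- matrix(rnorm(19 * 40), nrow = 40)
  rs <- morphowrap:::rank_sum_rows(M, 10, 9)
  expect_true(all(rs$method == "exact"))
  pref <- apply(M, 1, function(r) wilcox.test(r[1:10], r[11:19])$p.value)
  expect_equal(rs$p, pref, tolerance = 1e-12)

  # tied / large-sample path against wilcox.test's corrected approximation
  Mt <- matrix(sample(1:6, 30 * 25, TRUE), nrow = 25)
  rst <- morphowrap:::rank_sum_rows(Mt, 14, 16)
  expect_true(all(rst$method == "normal-approx"))
  preft <- apply(Mt, 1, function(r) suppressWarnings(
    wilcox.test(r[1:14], r[15:30])$p.value))
  expect_equal(rst$p, preft, tolerance = 1e-12)

  # enumeration oracle across all small group sizes
  for (n1 in 2:5) for (n2 in 2:(min(5, 10 - n1))) {
    x <- rnorm(n1); y <- rnorm(n2)
    got <- morphowrap:::rank_sum_rows(matrix(c(x, y), 1), n1, n2)$p
    expect_equal(got, ranksum_enumerate(x, y), tolerance = 1e-12)
  }
  expect_equal(morphowrap:::rank_sum_rows(matrix(1:6, 1), 3, 3)$p, 0.1)
})

test_that("wilcoxon_map is symmetric, handles validity and identical data", {
  set.seed(25)
  ga <- lapply(1:5, function(i) random_cast(30))
  gb <- lapply(1:4, function(i) random_cast(30))
  ga[[2]]$valid[4] <- FALSE
  res <- wilcoxon_map(ga, gb)
  expect_equal(sort(unique(res$axis)), c("x", "y", "z"))
  expect_equal(nrow(res), 3 * 29) # id 3 dropped everywhere
  expect_false(3 %in% res$id)
  expect_true(all(res$n1 == 5 & res$n2 == 4))

  swapped <- wilcoxon_map(gb, ga)
  expect_equal(res$p,
               swapped$p[match(paste(res$id, res$axis),
                               paste(swapped$id, swapped$axis))],
               tolerance = 1e-12)

  same <- wilcoxon_map(ga[1:2], ga[1:2])
  expect_true(all(same$p == 1))
})

test_that("storey pi0 estimation brackets known null fractions", {
  set.seed(26)
  p_null <- runif(10000)
  f1 <- storey_qvalues(p_null)
  expect_gte(f1$pi0, 0.90)
  expect_lte(f1$pi0, 1.0)
  expect_equal(f1$pi1, 1 - f1$pi0)

  p_mix <- c(runif(3000, 0, 1e-4), runif(7000))
  f2 <- storey_qvalues(p_mix)
  expect_gte(f2$pi0, 0.6)
  expect_lte(f2$pi0, 0.8)

  tiny <- rep(1e-8, 1000)
  f3 <- storey_qvalues(tiny)
  expect_true(all(f3$q <= f3$pi0 * 1000 * 1e-8 + 1e-15))
  expect_true(all(diff(f3$q[order(f3$p)]) >= -1e-15))

  expect_error(storey_qvalues(runif(5)), "too few")
  expect_error(storey_qvalues(c(0.5, -0.1, rep(0.5, 10))), "within")
})

test_that("q-values reduce to BH with pi0 = 1 and stay order-consistent", {
  set.seed(27)
  p <- runif(500)^2
  f <- storey_qvalues(p, pi0 = 1)
  expect_equal(f$q, p.adjust(p, "BH"), tolerance = 1e-12)

  fs <- storey_qvalues(p)
  o <- order(p)
  expect_true(all(diff(fs$q[o]) >= -1e-15))
  expect_true(all(fs$q >= 0 & fs$q <= 1))
})

test_that("per-axis q-value maps carry pi0 summaries", {
  set.seed(28)
  ga <- lapply(1:5, function(i) random_cast(60))
  gb <- lapply(1:5, function(i) {
    c_ <- random_cast(60)
    c_$z <- c_$z + 500 # strong z-only group effect
    c_
  })
  res <- qvalue_map(wilcoxon_map(ga, gb))
  expect_true("q" %in% names(res))
  s <- fdr_summary(res)
  expect_equal(s$axis, c("x", "y", "z"))
  expect_true(all(s$pi0 > 0 & s$pi0 <= 1))
  expect_lt(s$pi0[3], s$pi0[1]) # z must look far less null than x
})

test_that("significance counting respects strict thresholds", {
  tr <- tibble::tibble(id = rep(0:2, 3), axis = rep(c("x", "y", "z"), each = 3),
                       p = c(0.005, 0.02, 0.009, rep(0.5, 6)))
  sc <- significance_counts(tr, 0.01)
  expect_equal(sc$n_significant[sc$axis == "x"], 2L)
  expect_equal(sc$n_significant[sc$axis == "y"], 0L)
  expect_equal(sc$n_tested, rep(3L, 3))
  all_in <- significance_counts(tr, 1)
  expect_equal(all_in$n_significant, rep(3L, 3))
})
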