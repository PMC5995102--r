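#' Per-point confidence ellipsoids of a group
#'
#' For every id valid in all casts of the group, an axis-aligned ellipsoid
#' centred at the group mean position whose radii are the per-axis
#' confidence-interval half-widths. By default these are CIs of the *mean*,
#' `t(1-(1-ci)/2, n-1) * s / sqrt(n)`; `ci_kind = "observation"` instead
#' uses prediction-interval half-widths `t * s * sqrt(1 + 1/n)`.
#'
#' @param group list of aligned casts, at least 2.
#' @param ci_level confidence level in \[0, 1).
#' @param ci_kind `"mean"` (default) or `"observation"`.
#' @return A tibble of class `ellipsoid_set`: `id, x, y, z, rx, ry, rz, n`.
#' @export
confidence_ellipsoids <- function(group, ci_level = 0.95,
                                  ci_kind = c("mean", "observation")) {
  ci_kind <- match.arg(ci_kind)
  group <- lapply(group, as_cast_df)
  n <- length(group)
  if (n < 2) abort("need at least 2 casts for confidence ellipsoids")
  if (ci_level < 0 || ci_level >= 1) abort("ci_level must be in [0, 1)")
  ids <- group[[1]]$id
  valid <- Reduce(`&`, lapply(group, function(c_) c_$valid[match(ids, c_$id)]))
  ids <- ids[valid]
  arr <- lapply(c("x", "y", "z"), function(ax) {
    vapply(group, function(c_) c_[[ax]][match(ids, c_$id)], numeric(length(ids)))
  })
  tq <- qt(1 - (1 - ci_level) / 2, df = n - 1)
  mult <- if (ci_kind == "mean") tq / sqrt(n) else tq * sqrt(1 + 1 / n)
  ctr <- lapply(arr, rowMeans)
  rad <- lapply(arr, function(M) apply(M, 1, sd) * mult)
  out <- tibble(id = ids, x = ctr[[1]], y = ctr[[2]], z = ctr[[3]],
                rx = rad[[1]], ry = rad[[2]], rz = rad[[3]], n = n)
  class(out) <- c("ellipsoid_set", class(out))
  out
}

#' Do two axis-aligned ellipsoids intersect?
#'
#' Tests whether the closed ellipsoids
#' \eqn{\sum_j ((x_j - c_j)/r_j)^2 \le 1} intersect. Quick accept when
#' either centre lies in the other ellipsoid; quick reject when the
#' bounding slabs are disjoint on any axis; otherwise the second
#' ellipsoid's quadratic form is minimised over the first ellipsoid via the
#' one-dimensional Lagrange-multiplier root (coordinates decouple for
#' axis-aligned forms; bisection to 1e-12) and overlap holds iff the
#' minimum is at most 1. Touching counts as overlap. Zero radii collapse
#' the corresponding axis (points, segments and discs are allowed).
#'
#' @param center1,center2 numeric length-3 centres (micrometres).
#' @param radii1,radii2 numeric length-3 non-negative radii.
#' @param tol numerical slack for the touching case.
#' @return `TRUE` if the ellipsoids overlap (including tangency).
#' @export
ellipsoid_overlap <- function(center1, radii1, center2, radii2, tol = 1e-9) {
  c1 <- as.numeric(center1); c2 <- as.numeric(center2)
  r1 <- as.numeric(radii1); r2 <- as.numeric(radii2)
  if (any(r1 < 0) || any(r2 < 0)) abort("negative ellipsoid radius")
  # disjoint bounding slabs
  if (any(abs(c1 - c2) > r1 + r2 + tol)) return(FALSE)
  # centre-in-other quick accepts
  if (qform_point(c2, c1, r1) <= 1 + tol) return(TRUE)
  if (qform_point(c1, c2, r2) <= 1 + tol) return(TRUE)
  min_q2_over_e1(c1, r1, c2, r2, tol) <= 1 + tol
}

# value of sum(((p - c)/r)^2) with 0-radius axes treated as constraints
qform_point <- function(p, c_, r) {
  d <- p - c_
  q <- 0
  for (j in seq_along(d)) {
    if (r[j] == 0) {
      if (abs(d[j]) > 0) return(Inf)
    } else q <- q + (d[j] / r[j])^2
  }
  q
}

# minimum of ellipsoid-2 quadratic form over ellipsoid 1 (Lagrange/bisection)
min_q2_over_e1 <- function(c1, r1, c2, r2, tol = 1e-9) {
  fixed2 <- r2 == 0 # x_j forced to c2_j for membership in E2
  budget <- 1
  const_q2 <- 0
  for (j in which(fixed2)) {
    if (r1[j] == 0) {
      if (abs(c1[j] - c2[j]) > tol) return(Inf)
    } else budget <- budget - ((c2[j] - c1[j]) / r1[j])^2
  }
  if (budget < -tol) return(Inf) # E1 has no point with those coordinates
  budget <- max(budget, 0)
  free <- !fixed2
  fixed1 <- free & (r1 == 0) # x_j forced to c1_j inside E1
  for (j in which(fixed1)) const_q2 <- const_q2 + ((c1[j] - c2[j]) / r2[j])^2
  j_free <- which(free & !fixed1)
  if (length(j_free) == 0) return(const_q2)
  a1 <- c1[j_free]; b1 <- r1[j_free]
  a2 <- c2[j_free]; b2 <- r2[j_free]
  g <- function(nu) { # residual of E1 constraint at the stationary point
    x <- (a2 * b1^2 + nu * a1 * b2^2) / (b1^2 + nu * b2^2)
    sum(((x - a1) / b1)^2)
  }
  if (g(0) <= budget) { # unconstrained minimum already inside E1
    return(const_q2)
  }
  lo <- 0; hi <- 1
  while (g(hi) > budget && hi < 1e12) hi <- hi * 2
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > budget) lo <- mid else hi <- mid
    if (hi - lo < 1e-12 * max(1, hi)) break
  }
  nu <- hi
  x <- (a2 * b1^2 + nu * a1 * b2^2) / (b1^2 + nu * b2^2)
  const_q2 + sum(((x - a2) / b2)^2)
}

#' Overlap map between two ellipsoid sets
#'
#' Per shared id, tests whether the two groups' confidence ellipsoids
#' overlap. No overlap suggests a localised statistical difference and is
#' coloured black; overlap is coloured purple.
#'
#' @param set_a,set_b `ellipsoid_set` tibbles; the verdict is computed on
#'   the ids tested in both (an error if the sets share none).
#' @return A tibble of class `overlap_result`: `id, overlap, colour`.
#' @export
overlap_map <- function(set_a, set_b) {
  common <- intersect(set_a$id, set_b$id)
  if (length(common) == 0)
    abort("ellipsoid sets share no tested ids")
  a <- set_a[match(common, set_a$id), ]
  b <- set_b[match(common, set_b$id), ]
  ca <- as.matrix(a[, c("x", "y", "z")]); cb <- as.matrix(b[, c("x", "y", "z")])
  ra <- as.matrix(a[, c("rx", "ry", "rz")]); rb <- as.matrix(b[, c("rx", "ry", "rz")])
  tol <- 1e-9
  d <- abs(ca - cb)
  reject <- rowSums(d > ra + rb + tol) > 0 # disjoint slab on some axis
  qa_in_b <- rowSums(((ca - cb) / replace(rb, rb == 0, Inf))^2 +
                       ifelse(rb == 0 & d > 0, Inf, 0)) <= 1 + tol
  qb_in_a <- rowSums(((cb - ca) / replace(ra, ra == 0, Inf))^2 +
                       ifelse(ra == 0 & d > 0, Inf, 0)) <= 1 + tol
  overlap <- rep(NA, length(common))
  overlap[reject] <- FALSE
  overlap[!reject & (qa_in_b | qb_in_a)] <- TRUE
  todo <- which(is.na(overlap))
  for (i in todo) {
    overlap[i] <- ellipsoid_overlap(ca[i, ], ra[i, ], cb[i, ], rb[i, ], tol)
  }
  out <- tibble(id = common, overlap = overlap,
                colour = ifelse(overlap, "purple", "black"))
  class(out) <- c("overlap_result", class(out))
  out
}

#' Permutation validation of the ellipsoid overlap test
#'
#' Repeatedly exchanges `floor(fraction * min(nA, nB))` randomly chosen
#' casts between the two groups (group sizes stay fixed), recomputes both
#' groups' confidence ellipsoids and the overlap map. A genuine group
#' effect should dissolve into (nearly) all-purple maps under permutation.
#'
#' @param casts list of casts (both groups together).
#' @param labels character/factor of two group labels, one per cast.
#' @param fraction fraction of the smaller group to swap each way.
#' @param n_permutations number of permutations (default 3).
#' @param seed integer RNG seed.
#' @param ci_level,ci_kind passed to [confidence_ellipsoids()].
#' @return A list of `overlap_result` tibbles, one per permutation, each
#'   with the swapped indices in attribute `swapped`.
#' @export
permute_and_test <- function(casts, labels, fraction = 0.5,
                             n_permutations = 3, seed = 1L,
                             ci_level = 0.95, ci_kind = "mean") {
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2) abort("labels must contain exactly two groups")
  if (fraction <= 0 || fraction > 1) abort("fraction must be in (0, 1]")
  ia <- which(labels == lv[1]); ib <- which(labels == lv[2])
  k <- floor(fraction * min(length(ia), length(ib)))
  if (k == 0) abort("fraction swaps zero casts")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()), add = TRUE)
  set.seed(seed)
  lapply(seq_len(n_permutations), function(perm) {
    swap_a <- sample(ia, k); swap_b <- sample(ib, k)
    new_a <- c(setdiff(ia, swap_a), swap_b)
    new_b <- c(setdiff(ib, swap_b), swap_a)
    ea <- confidence_ellipsoids(casts[new_a], ci_level, ci_kind)
    eb <- confidence_ellipsoids(casts[new_b], ci_level, ci_kind)
    om <- overlap_map(ea, eb)
    attr(om, "swapped") <- list(from_a = swap_a, from_b = swap_b)
    om
  })
}
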