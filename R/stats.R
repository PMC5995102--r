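#' Group mean model
#'
#' Per-id arithmetic mean of x, y and z over all casts of an (aligned)
#' group. An id is valid in the model only if it is valid in *every*
#' member, so each retained point averages the same number of specimens.
#'
#' @param casts a list of aligned casts (e.g. an `aligned_group`).
#' @return A tibble of class `mw_cast` with columns `id, x, y, z, valid,
#'   n_used`.
#' @export
mean_model <- function(casts) {
  if (is.data.frame(casts)) casts <- list(casts)
  if (length(casts) == 0) abort("empty group")
  casts <- lapply(casts, as_cast_df)
  ids <- casts[[1]]$id
  for (c_ in casts[-1]) if (!identical(sort(c_$id), sort(ids)))
    abort("casts do not share one template")
  n <- length(casts)
  valid <- Reduce(`&`, lapply(casts, function(c_) c_$valid[match(ids, c_$id)]))
  acc <- matrix(0, length(ids), 3)
  for (c_ in casts) {
    m <- as.matrix(c_[match(ids, c_$id), c("x", "y", "z")])
    m[is.na(m)] <- 0
    acc <- acc + m
  }
  acc <- acc / n
  out <- new_cast(ids, ifelse(valid, acc[, 1], NA_real_),
                  ifelse(valid, acc[, 2], NA_real_),
                  ifelse(valid, acc[, 3], NA_real_), valid,
                  n_rows = attr(casts[[1]], "n_rows") %||% NA_integer_,
                  n_cols = attr(casts[[1]], "n_cols") %||% NA_integer_)
  out$n_used <- ifelse(valid, n, 0L)
  out
}

#' Displacement field between two models
#'
#' `other` is first Procrustes-fit onto `reference` (partial fit by
#' default; set `allow_scaling = TRUE` to remove size first), then per-id
#' coordinate differences `other - reference` are taken on the shared valid
#' ids and the displacement magnitude follows from the Pythagorean theorem.
#' All values in micrometres.
#'
#' @param reference_model,other_model casts or mean models.
#' @param allow_scaling remove uniform size before differencing?
#' @return A tibble of class `displacement_field`: `id, x, y, z` (reference
#'   position), `dx, dy, dz, magnitude`.
#' @export
displacement_field <- function(reference_model, other_model,
                               allow_scaling = FALSE) {
  fit <- procrustes(reference_model, other_model, allow_scaling = allow_scaling)
  ref <- as_cast_df(reference_model, "reference_model")
  oth <- fit$aligned
  common <- intersect(ref$id[ref$valid], oth$id[oth$valid])
  a <- ref[match(common, ref$id), ]
  b <- oth[match(common, oth$id), ]
  out <- tibble(id = common, x = a$x, y = a$y, z = a$z,
                dx = b$x - a$x, dy = b$y - a$y, dz = b$z - a$z)
  out$magnitude <- sqrt(out$dx^2 + out$dy^2 + out$dz^2)
  attr(out, "procrustes") <- fit[c("rotation", "translation", "scale", "distance")]
  class(out) <- c("displacement_field", class(out))
  out
}

#' Dense point-wise Wilcoxon rank-sum test field
#'
#' For every grid id valid in *all* casts of both groups, a two-sided
#' Mann-Whitney/Wilcoxon rank-sum test is run separately on the x, y and z
#' coordinates, comparing the two groups of specimens (so three tests per
#' retained id). The exact null distribution is used when
#' `n1 + n2 <= exact_limit` and the coordinates are tie-free; otherwise the
#' normal approximation with tie and continuity correction. Groups must be
#' aligned to a common prototype beforehand.
#'
#' @param group_a,group_b lists of aligned casts.
#' @param exact_limit largest combined group size for the exact null.
#' @return A tibble of class `pointwise_tests`: `id, axis, p, n1, n2,
#'   method`.
#' @export
wilcoxon_map <- function(group_a, group_b, exact_limit = 25L) {
  ga <- lapply(group_a, as_cast_df)
  gb <- lapply(group_b, as_cast_df)
  if (length(ga) == 0 || length(gb) == 0) abort("both groups need casts")
  ids <- ga[[1]]$id
  shared <- Reduce(`&`, lapply(c(ga, gb),
                               function(c_) c_$valid[match(ids, c_$id)]))
  ids <- ids[shared]
  if (length(ids) == 0) abort("no id is valid in every cast of both groups")
  n1 <- length(ga); n2 <- length(gb)
  # build n_ids x (n1+n2) coordinate matrices per axis
  all_casts <- c(ga, gb)
  take <- function(ax) vapply(all_casts, function(c_) {
    c_[[ax]][match(ids, c_$id)]
  }, numeric(length(ids)))
  out <- purrr::map_dfr(c("x", "y", "z"), function(ax) {
    M <- take(ax)
    rs <- rank_sum_rows(M, n1, n2, exact_limit)
    tibble(id = ids, axis = ax, p = rs$p, n1 = n1, n2 = n2,
           method = rs$method)
  })
  class(out) <- c("pointwise_tests", class(out))
  out
}

# vectorised two-sided rank-sum p-values for each row of M (first n1
# columns = group A); exact via pwilcox when tie-free and small, else
# normal approximation with tie + continuity correction (ranksum-style)
rank_sum_rows <- function(M, n1, n2, exact_limit = 25L) {
  N <- n1 + n2
  stopifnot(ncol(M) == N)
  ranks <- t(apply(M, 1, rank))
  if (N == 1) ranks <- matrix(ranks, ncol = 1)
  W <- rowSums(ranks[, seq_len(n1), drop = FALSE])
  U <- W - n1 * (n1 + 1) / 2
  ties <- apply(M, 1, anyDuplicated) > 0
  exact <- (N <= exact_limit) & !ties
  p <- rep(NA_real_, nrow(M))
  if (any(exact)) {
    u <- U[exact]
    lower <- pwilcox(u, n1, n2)
    upper <- pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    p[exact] <- pmin(2 * pmin(lower, upper), 1)
  }
  if (any(!exact)) {
    idx <- which(!exact)
    z <- U[idx] - n1 * n2 / 2
    tiecor <- vapply(idx, function(i) {
      tt <- table(M[i, ])
      sum(tt^3 - tt)
    }, numeric(1))
    sigma <- sqrt((n1 * n2 / 12) * ((N + 1) - tiecor / (N * (N - 1))))
    z <- (z - sign(z) * 0.5) / sigma
    p[idx] <- pmin(2 * pmin(pnorm(z), pnorm(z, lower.tail = FALSE)), 1)
  }
  list(p = p, method = ifelse(exact, "exact", "normal-approx"))
}

#' Storey q-values with smoothed pi0 estimate
#'
#' Estimates the null proportion pi0 on the lambda grid
#' `0, 0.01, ..., 0.95` as `#\{p > lambda\} / (m (1 - lambda))`, smooths
#' the curve with a cubic polynomial in lambda, evaluates it at the largest
#' lambda and clips to (0, 1]. Q-values follow by the step-up rule
#' `q(p_(m)) = pi0 p_(m)`, `q(p_(i)) = min(pi0 m p_(i) / i, q(p_(i+1)))`.
#' `pi1 = 1 - pi0` is a lower bound on the fraction of tests that truly
#' follow the alternative. Forcing `pi0 = 1` reduces the procedure to
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param p numeric vector of at least 10 finite p-values in \[0, 1\].
#' @param lambda grid of lambda values for pi0 estimation.
#' @param pi0 optional fixed null proportion overriding the estimate.
#' @return An object of class `storey_fdr`: `q` (order-matching `p`),
#'   `pi0`, `pi1`, `lambda`, `pi0_lambda`.
#' @export
storey_qvalues <- function(p, lambda = seq(0, 0.95, by = 0.01), pi0 = NULL) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    abort("p-values must be finite and within [0, 1]")
  m <- length(p)
  pi0_lambda <- NULL
  if (is.null(pi0)) {
    if (m < 10) abort("too few tests for pi0 smoothing (need >= 10)")
    pi0_lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- lm(pi0_lambda ~ poly(lambda, 3))
    pi0 <- predict(fit, newdata = data.frame(lambda = max(lambda)))[[1]]
    pi0 <- min(max(pi0, 1e-8), 1)
  } else {
    if (pi0 <= 0 || pi0 > 1) abort("pi0 must be in (0, 1]")
  }
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  structure(list(q = q, p = p, pi0 = pi0, pi1 = 1 - pi0, m = m,
                 lambda = lambda, pi0_lambda = pi0_lambda),
            class = "storey_fdr")
}

#' @export
print.storey_fdr <- function(x, ...) {
  cat(sprintf("<storey_fdr: m = %d, pi0 = %.4f, pi1 = %.4f>\n",
              x$m, x$pi0, x$pi1))
  invisible(x)
}

#' @rdname storey_qvalues
#' @param x a `storey_fdr` object.
#' @param ... unused.
#' @export
tidy.storey_fdr <- function(x, ...) tibble(p = x$p, q = x$q)

#' @rdname storey_qvalues
#' @export
glance.storey_fdr <- function(x, ...) {
  tibble(m = x$m, pi0 = x$pi0, pi1 = x$pi1)
}

#' Attach per-axis q-values to a point-wise test field
#'
#' Runs [storey_qvalues()] separately for each coordinate axis (multiple
#' testing is controlled within, not across, axes).
#'
#' @param test_result a `pointwise_tests` tibble from [wilcoxon_map()].
#' @param ... passed to [storey_qvalues()].
#' @return The input with a `q` column added; per-axis `pi0`/`pi1` are
#'   available via [fdr_summary()] (attribute `fdr`).
#' @export
qvalue_map <- function(test_result, ...) {
  stopifnot(all(c("id", "axis", "p") %in% names(test_result)))
  parts <- split(test_result, test_result$axis)
  fits <- lapply(parts, function(df) storey_qvalues(df$p, ...))
  out <- dplyr::bind_rows(lapply(names(parts), function(ax) {
    df <- parts[[ax]]
    df$q <- fits[[ax]]$q
    df
  }))
  out <- dplyr::arrange(out, .data$axis, .data$id)
  attr(out, "fdr") <- dplyr::bind_rows(lapply(names(fits), function(ax) {
    tibble(axis = ax, pi0 = fits[[ax]]$pi0, pi1 = fits[[ax]]$pi1,
           m = fits[[ax]]$m)
  }))
  class(out) <- unique(c("pointwise_tests", class(out)))
  out
}

#' @rdname qvalue_map
#' @param result a tibble returned by `qvalue_map`.
#' @export
fdr_summary <- function(result) {
  s <- attr(result, "fdr")
  if (is.null(s)) abort("no FDR summary attached; run qvalue_map() first")
  s
}

#' Count significant points per axis
#'
#' @param test_result a `pointwise_tests` tibble.
#' @param p_threshold strict upper bound on p (default 0.01).
#' @param column which column to threshold (`"p"` or `"q"`).
#' @return A tibble `axis, n_significant, n_tested`.
#' @export
significance_counts <- function(test_result, p_threshold = 0.01,
                                column = "p") {
  if (p_threshold <= 0 || p_threshold > 1) abort("threshold must be in (0, 1]")
  test_result |>
    dplyr::group_by(.data$axis) |>
    dplyr::summarise(n_significant = sum(.data[[column]] < p_threshold),
                     n_tested = dplyr::n(), .groups = "drop")
}
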