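#' Procrustes superimposition of two casts
#'
#' Least-squares rigid (rotation + translation, optionally + uniform scale)
#' superimposition of `moving` onto `reference`, computed on the ids valid
#' in both casts and then applied to every valid point of `moving`.
#' Reflections are forbidden (specimens are all same-handed half bodies).
#' With `allow_scaling = FALSE` this is the partial Procrustes fit: size is
#' treated as data, not nuisance, and the centroid size of `moving` is
#' preserved. The reported `distance` is the partial (or full) Procrustes
#' distance: the minimal sum of squared point distances after the fit, in
#' square micrometres.
#'
#' @param reference,moving casts (or any tibble with `id, x, y, z, valid`)
#'   sharing at least 3 common valid, non-collinear ids.
#' @param allow_scaling if `TRUE`, a uniform scale is estimated as well.
#' @return An object of class `procrustes_fit` with elements `rotation`
#'   (3 x 3, det +1), `translation` (length 3, micrometres), `scale`
#'   (1 when scaling is disabled), `distance`, `aligned` (the transformed
#'   cast), `n_common`.
#' @export
procrustes <- function(reference, moving, allow_scaling = FALSE) {
  reference <- as_cast_df(reference, "reference")
  moving <- as_cast_df(moving, "moving")
  common <- intersect(reference$id[reference$valid], moving$id[moving$valid])
  if (length(common) < 3) abort("fewer than 3 common valid points")
  A <- as.matrix(reference[match(common, reference$id), c("x", "y", "z")])
  B <- as.matrix(moving[match(common, moving$id), c("x", "y", "z")])
  muA <- colMeans(A); muB <- colMeans(B)
  Ac <- sweep(A, 2, muA); Bc <- sweep(B, 2, muB)
  ssB <- sum(Bc^2)
  if (ssB < 1e-12 || sum(Ac^2) < 1e-12)
    abort("zero-variance configuration: cannot superimpose")
  sv <- svd(crossprod(Bc, Ac)) # minimise ||Ac - s Bc R||, R = U V' with det fix
  dsign <- c(1, 1, sign(det(sv$u %*% t(sv$v))))
  if (dsign[3] == 0) dsign[3] <- 1
  R <- sv$u %*% diag(dsign) %*% t(sv$v)
  if (svd(Ac)$d[2] < 1e-9 * svd(Ac)$d[1])
    abort("degenerate configuration: common points are collinear")
  s <- if (allow_scaling) sum(sv$d * dsign) / ssB else 1
  tvec <- muA - s * as.vector(muB %*% R)
  fit_res <- sum((Ac - s * Bc %*% R)^2)
  aligned <- moving
  vm <- as.matrix(moving[moving$valid, c("x", "y", "z")])
  vt <- s * vm %*% R + matrix(tvec, nrow(vm), 3, byrow = TRUE)
  aligned$x[aligned$valid] <- vt[, 1]
  aligned$y[aligned$valid] <- vt[, 2]
  aligned$z[aligned$valid] <- vt[, 3]
  structure(list(rotation = R, translation = tvec, scale = s,
                 distance = fit_res, aligned = aligned,
                 n_common = length(common), allow_scaling = allow_scaling),
            class = "procrustes_fit")
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat(sprintf(
    "<procrustes_fit: %d common points, scale %.6g, distance %.6g um^2>\n",
    x$n_common, x$scale, x$distance))
  invisible(x)
}

#' @rdname procrustes
#' @param x a `procrustes_fit`.
#' @param ... unused.
#' @export
tidy.procrustes_fit <- function(x, ...) {
  al <- x$aligned
  as_tibble(al[al$valid, c("id", "x", "y", "z")])
}

#' @rdname procrustes
#' @export
glance.procrustes_fit <- function(x, ...) {
  tibble(n_common = x$n_common, scale = x$scale, distance = x$distance,
         rmsd = sqrt(x$distance / x$n_common),
         allow_scaling = x$allow_scaling)
}

#' Align a group of casts to a prototype
#'
#' Every cast is independently superimposed onto the prototype (star
#' alignment; the prototype itself is returned unchanged). The prototype
#' should be a representative specimen: template regions it lacks are
#' dropped from the fit of every pair, and ids it lacks cannot enter the
#' downstream statistics.
#'
#' @param casts a (optionally named) list of casts sharing one template.
#' @param prototype index/name into `casts`, or a cast/mean model supplied
#'   directly. Defaults to the first cast.
#' @param allow_scaling passed to [procrustes()].
#' @return A list of aligned casts (class `aligned_group`) with the
#'   prototype recorded in attributes.
#' @export
align_group <- function(casts, prototype = 1L, allow_scaling = FALSE) {
  if (length(casts) < 1) abort("no casts to align")
  if (is.data.frame(prototype)) {
    proto <- as_cast_df(prototype, "prototype")
    proto_idx <- NA_integer_
  } else {
    proto_idx <- if (is.character(prototype)) match(prototype, names(casts))
      else as.integer(prototype)
    if (is.na(proto_idx) || proto_idx < 1 || proto_idx > length(casts))
      abort("prototype not found among casts")
    proto <- casts[[proto_idx]]
  }
  out <- lapply(seq_along(casts), function(i) {
    if (!is.na(proto_idx) && i == proto_idx) return(casts[[i]])
    procrustes(proto, casts[[i]], allow_scaling = allow_scaling)$aligned
  })
  names(out) <- names(casts)
  structure(out, class = "aligned_group", prototype = proto,
            allow_scaling = allow_scaling)
}
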