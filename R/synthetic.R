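#' Parameters of a synthetic half-body
#'
#' Describes a bilaterally halved, smooth, convex-ish body surface at the
#' millimetre scale: a half-superellipsoid trunk (z >= 0, the scanned
#' lateral half) with a tapered tail spine along the posterior body axis
#' and an optional smooth bump on the head region. The antero-posterior
#' axis is y (anterior positive), dorso-ventral is x, lateral (projection)
#' is z. All lengths in micrometres.
#'
#' @param body_length,body_height trunk extent along y and x.
#' @param half_width maximal lateral (z) extent of the half body.
#' @param spine_length length of the tail spine (posterior, along -y).
#' @param spine_radius spine radius at its base.
#' @param head_bump_amplitude amplitude of a smooth bump near the head.
#' @param exponent superellipse exponent (>= 2; 2 = ellipsoid).
#' @param extra_bumps optional list of lists `(u0, v0, amplitude, width)`
#'   adding localised Gaussian height offsets (used to encode localised
#'   group effects).
#' @return A list of class `body_params`.
#' @export
body_params <- function(body_length = 2400, body_height = 1600,
                        half_width = 550, spine_length = 700,
                        spine_radius = 90, head_bump_amplitude = 0,
                        exponent = 2.5, extra_bumps = list()) {
  p <- list(body_length = body_length, body_height = body_height,
            half_width = half_width, spine_length = spine_length,
            spine_radius = spine_radius,
            head_bump_amplitude = head_bump_amplitude,
            exponent = exponent, extra_bumps = extra_bumps)
  nums <- p[c("body_length", "body_height", "half_width", "spine_length",
              "spine_radius")]
  if (any(!vapply(nums, is.numeric, logical(1))) ||
        any(unlist(nums) < 0) || body_length <= 0 || body_height <= 0 ||
        half_width <= 0)
    abort("body dimensions must be positive")
  if (exponent < 2) abort("superellipse exponent must be >= 2")
  class(p) <- "body_params"
  p
}

#' A known group effect for synthetic populations
#'
#' Encodes how the treated (e.g. predator-exposed) group differs from the
#' control ideal: a global size factor (the dominant reaction of the real
#' system), a disproportionate elongation of the tail spine, an optional
#' localised bump offset on the head, and the sd of the smooth
#' per-individual positional noise shared by both groups.
#'
#' The defaults mirror the emulated study system: the dominant reaction is
#' a 10% increase in body size, with a modest disproportionate spine
#' elongation as the main genuine shape change and no localised offsets.
#'
#' @param global_scale uniform size factor (> 0).
#' @param spine_elongation extra spine length factor on top of the global
#'   scale (> 0).
#' @param head_bump_amplitude amplitude (um) of a localised head offset in
#'   the treated group (0 = none).
#' @param individual_noise_sd sd (um) of the per-individual positional
#'   noise field.
#' @return A list of class `group_effect`.
#' @export
group_effect <- function(global_scale = 1.1, spine_elongation = 1.15,
                         head_bump_amplitude = 0,
                         individual_noise_sd = 5) {
  if (global_scale <= 0 || spine_elongation <= 0)
    abort("effect factors must be positive")
  if (individual_noise_sd < 0) abort("noise sd must be >= 0")
  structure(list(global_scale = global_scale,
                 spine_elongation = spine_elongation,
                 head_bump_amplitude = head_bump_amplitude,
                 individual_noise_sd = individual_noise_sd),
            class = "group_effect")
}

#' @rdname group_effect
#' @param params a [body_params()] describing the control ideal.
#' @param effect a `group_effect`.
#' @return `apply_effect`: the [body_params()] of the treated ideal.
#' @export
apply_effect <- function(params, effect) {
  s <- effect$global_scale
  body_params(
    body_length = params$body_length * s,
    body_height = params$body_height * s,
    half_width = params$half_width * s,
    spine_length = params$spine_length * s * effect$spine_elongation,
    spine_radius = params$spine_radius * s,
    head_bump_amplitude = params$head_bump_amplitude +
      effect$head_bump_amplitude,
    exponent = params$exponent,
    extra_bumps = params$extra_bumps)
}

# analytic height field z(u, v) >= 0 of the half body; returns z and the
# silhouette membership flag. (u, v) = (x, y); body centred at the origin.
body_height_field <- function(params, u, v) {
  a <- params$body_length / 2
  b <- params$body_height / 2
  cw <- params$half_width
  e <- params$exponent
  rho <- (abs(u) / b)^e + (abs(v) / a)^e
  z_body <- ifelse(rho <= 1, cw * pmax(1 - rho, 0)^(1 / e), -Inf)
  # tapered spine along -y from the posterior pole; the tip is blunt
  # (quarter of the base radius) as in the real structure, which also
  # keeps the full spine length representable at finite mesh resolution
  z_spine <- rep(-Inf, length(u))
  if (params$spine_length > 0 && params$spine_radius > 0) {
    y0 <- -a + params$spine_radius # root tucked into the trunk
    tipy <- -a - params$spine_length
    tt <- (v - tipy) / (y0 - tipy)
    in_y <- tt >= 0 & tt <= 1
    rr <- params$spine_radius * pmax(0.25 + 0.75 * pmax(tt, 0), 0)
    in_spine <- in_y & abs(u) <= rr
    z_spine[in_spine] <- sqrt(pmax(rr[in_spine]^2 - u[in_spine]^2, 0))
  }
  z <- pmax(z_body, z_spine)
  inside <- is.finite(z)
  # smooth bumps (head + any extras) raise the surface locally
  bumps <- params$extra_bumps
  if (params$head_bump_amplitude != 0) {
    bumps <- c(bumps, list(list(u0 = 0, v0 = 0.75 * a,
                                amplitude = params$head_bump_amplitude,
                                width = 0.25 * a)))
  }
  for (bp in bumps) {
    z <- z + ifelse(inside,
                    bp$amplitude *
                      exp(-((u - bp$u0)^2 + (v - bp$v0)^2) / (2 * bp$width^2)),
                    0)
  }
  list(z = ifelse(inside, z, NA_real_), inside = inside)
}

#' Generate a synthetic half-body mesh with canonical landmarks
#'
#' Triangulates the analytic height field of the body over a fine lattice,
#' giving a single z-valued surface over its silhouette (so the
#' shrink-wrap projection is unambiguous), and returns at least five named
#' 2D landmarks on recurring outline features (spine tip and base, head
#' vertex, dorsal/ventral apices, rostrum).
#'
#' @param params a [body_params()].
#' @param mesh_step lattice step for triangulation, micrometres.
#' @return A list with `mesh` (a [triangle_mesh()]), `landmarks`
#'   (tibble `name, u, v`) and `params`.
#' @export
make_half_body <- function(params, mesh_step = 20) {
  stopifnot(inherits(params, "body_params"))
  a <- params$body_length / 2
  b <- params$body_height / 2
  us <- seq(-b - mesh_step, b + mesh_step, by = mesh_step)
  vs <- seq(-a - params$spine_length - mesh_step, a + mesh_step,
            by = mesh_step)
  nu <- length(us); nv <- length(vs)
  uu <- rep(us, times = nv); vv <- rep(vs, each = nu)
  hf <- body_height_field(params, uu, vv)
  idx <- matrix(seq_along(uu), nu, nv)
  inside <- matrix(hf$inside, nu, nv)
  verts <- cbind(uu, vv, ifelse(hf$inside, hf$z, 0))
  faces <- list()
  i00 <- idx[-nu, -nv]; i10 <- idx[-1, -nv]; i01 <- idx[-nu, -1]; i11 <- idx[-1, -1]
  b00 <- inside[-nu, -nv]; b10 <- inside[-1, -nv]; b01 <- inside[-nu, -1]
  b11 <- inside[-1, -1]
  all4 <- b00 & b10 & b01 & b11
  faces[[1]] <- cbind(i00[all4], i10[all4], i11[all4])
  faces[[2]] <- cbind(i00[all4], i11[all4], i01[all4])
  tri3 <- function(ba, bb, bc, ia, ib, ic) {
    sel <- ba & bb & bc & !all4
    cbind(ia[sel], ib[sel], ic[sel])
  }
  faces[[3]] <- tri3(b00, b10, b11, i00, i10, i11)
  faces[[4]] <- tri3(b00, b11, b01, i00, i11, i01)
  faces[[5]] <- tri3(b00, b10, b01, i00, i10, i01)
  faces[[6]] <- tri3(b10, b11, b01, i10, i11, i01)
  fmat <- do.call(rbind, faces)
  used <- sort(unique(as.vector(fmat)))
  remap <- match(seq_along(uu), used)
  mesh <- triangle_mesh(verts[used, , drop = FALSE],
                        matrix(remap[fmat], ncol = 3))
  list(mesh = mesh, landmarks = body_landmarks(params), params = params)
}

#' Canonical 2D landmarks of a synthetic half body
#'
#' Named outline (semi-)landmarks in the grid plane: tail-spine tip and
#' base, head vertex, dorsal and ventral apices, rostrum and the
#' heart-region indentation analogue.
#'
#' @param params a [body_params()].
#' @return A tibble `name, u, v` (micrometres).
#' @export
body_landmarks <- function(params) {
  a <- params$body_length / 2
  b <- params$body_height / 2
  e <- params$exponent
  # superellipse point at parametric angle t: (b sgn(cos) |cos|^(2/e), ...)
  se <- function(t) c(b * sign(cos(t)) * abs(cos(t))^(2 / e),
                      a * sign(sin(t)) * abs(sin(t))^(2 / e))
  outline <- t(vapply(pi * c(1 / 8, 3 / 8, 5 / 8, 7 / 8, 9 / 8, 11 / 8,
                             13 / 8, 15 / 8), se, numeric(2)))
  rostrum <- se(3 * pi / 4)
  heart <- se(7 * pi / 4)
  tibble(
    name = c("spine_tip", "spine_base", "head_vertex", "dorsal_apex",
             "ventral_apex", "rostrum", "heart_indent",
             sprintf("outline_%d", 1:8)),
    u = c(0, 0, 0, b, -b, rostrum[1], heart[1], outline[, 1]),
    v = c(-a - params$spine_length, -a, a, 0, 0, rostrum[2], heart[2],
          outline[, 2]))
}

# per-individual positional noise: a smooth low-order random field
# (biological variation, spatially correlated) plus independent per-point
# jitter (measurement/projection error), mixed by variance fraction
noise_field <- function(u, v, sd_target, smooth_frac = 0.1, order = 3) {
  if (sd_target == 0) return(numeric(length(u)))
  un <- (u - min(u)) / max(diff(range(u)), 1e-9)
  vn <- (v - min(v)) / max(diff(range(v)), 1e-9)
  f <- numeric(length(u))
  for (k in 0:order) for (l in 0:order) {
    if (k == 0 && l == 0) next
    f <- f + rnorm(1) * cos(pi * k * un + runif(1, 0, 2 * pi)) *
      cos(pi * l * vn + runif(1, 0, 2 * pi))
  }
  f <- f - mean(f)
  s <- sd(f)
  smooth <- if (s < 1e-12) numeric(length(u)) else f / s
  sd_target * (sqrt(smooth_frac) * smooth +
                 sqrt(1 - smooth_frac) * rnorm(length(u)))
}

random_rigid_motion <- function(max_angle = 20 * pi / 180, trans_sd = 100) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, -max_angle, max_angle)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  list(R = R, t = rnorm(3, 0, trans_sd))
}

apply_rigid <- function(cast, motion) {
  m <- as.matrix(cast[cast$valid, c("x", "y", "z")])
  m <- m %*% t(motion$R) + matrix(motion$t, nrow(m), 3, byrow = TRUE)
  cast$x[cast$valid] <- m[, 1]
  cast$y[cast$valid] <- m[, 2]
  cast$z[cast$valid] <- m[, 3]
  cast
}

# exact cast of the analytic body surface: the template grid is first
# warped (TPS) from the reference body's landmarks onto this body's
# landmarks — the per-specimen grid-adjustment step — then the height
# field is evaluated at the warped positions
ideal_cast <- function(params, grid, reference_params = NULL) {
  g <- grid
  if (!is.null(reference_params) && !identical(reference_params, params)) {
    src <- body_landmarks(reference_params)
    dst <- body_landmarks(params)
    g <- tps_warp(grid, tibble(u_template = src$u, v_template = src$v,
                               u_specimen = dst$u, v_specimen = dst$v))
  }
  hf <- body_height_field(params, g$u, g$v)
  dims <- grid_dims(grid)
  new_cast(grid$id, g$u, g$v, hf$z, hf$inside,
           n_rows = dims[1], n_cols = dims[2])
}

#' Generate a synthetic two-group cast population with known truth
#'
#' Control casts sample the analytic surface of `base` at the template
#' grid; treated casts sample the surface of `base` transformed by
#' `effect`, with the template grid first TPS-warped onto the treated
#' body's landmarks — the synthetic analogue of the per-specimen grid
#' adjustment, which is what carries group differences into the in-plane
#' (x, y) coordinates of homologous ids. Each individual then receives a
#' positional noise field (sd `effect$individual_noise_sd`, independent
#' per coordinate axis; a spatially smooth biological-variation component
#' plus per-point measurement jitter) and a random rigid displacement, so
#' the downstream Procrustes stage is genuinely exercised. The generator
#' truth is the noiseless displacement field between the two group ideals
#' after the partial (no scaling) Procrustes fit.
#'
#' @param base a [body_params()] for the control ideal.
#' @param effect a [group_effect()].
#' @param n_control,n_treated group sizes (>= 2).
#' @param seed integer RNG seed; populations are bit-identical for a fixed
#'   seed.
#' @param grid template grid; defaults to a 200 x 160 lattice covering the
#'   control silhouette with a small margin.
#' @return A list of class `synthetic_population`: `control`, `treated`
#'   (lists of casts), `truth` (a `displacement_field`), `grid`,
#'   `params_control`, `params_treated`.
#' @export
make_population <- function(base = body_params(), effect = group_effect(),
                            n_control = 10, n_treated = 9, seed = 1L,
                            grid = NULL) {
  stopifnot(inherits(base, "body_params"), inherits(effect, "group_effect"))
  if (n_control < 2 || n_treated < 2) abort("need at least 2 casts per group")
  treated_params <- apply_effect(base, effect)
  if (is.null(grid)) {
    a <- base$body_length / 2
    b <- base$body_height / 2
    L <- base$spine_length
    m <- 0.03 * (a + L)
    grid <- build_grid(200, 160, c(-b - m, b + m, -a - L - m, a + m))
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()), add = TRUE)
  set.seed(seed)
  noise_sd <- effect$individual_noise_sd
  make_one <- function(params) {
    cast <- ideal_cast(params, grid, reference_params = base)
    v <- cast$valid
    for (ax in c("x", "y", "z")) {
      cast[[ax]][v] <- cast[[ax]][v] +
        noise_field(cast$x[v], cast$y[v], noise_sd)
    }
    apply_rigid(cast, random_rigid_motion())
  }
  control <- lapply(seq_len(n_control), function(i) make_one(base))
  treated <- lapply(seq_len(n_treated), function(i) make_one(treated_params))
  truth <- displacement_field(ideal_cast(base, grid),
                              ideal_cast(treated_params, grid,
                                         reference_params = base),
                              allow_scaling = FALSE)
  structure(list(control = control, treated = treated, truth = truth,
                 grid = grid, params_control = base,
                 params_treated = treated_params, seed = seed),
            class = "synthetic_population")
}
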