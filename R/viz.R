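#' Map per-point values to heat-map colours
#'
#' Implements the study's colour semantics with linear RGB interpolation
#' between qualitative anchor colours:
#' \describe{
#'   \item{magnitude}{blue (small) through yellow to red (large) over the
#'     data range;}
#'   \item{signed}{blue (negative) through a pale neutral at exactly 0 to
#'     red (positive), symmetric about 0;}
#'   \item{pvalue / qvalue}{red-to-green gradient for values strictly below
#'     the threshold (red = most significant), yellow-to-blue above it
#'     (defaults: p 0.01, q 0.005);}
#'   \item{overlap}{purple for overlap, black for non-overlap, exactly.}
#' }
#'
#' @param values numeric (or logical, for `overlap`) vector; must be finite
#'   at every tested point.
#' @param kind one of `"magnitude"`, `"signed"`, `"pvalue"`, `"qvalue"`,
#'   `"overlap"`.
#' @param threshold significance threshold for the p/q kinds.
#' @return Character vector of hex colours, one per value.
#' @export
colorize <- function(values, kind = c("magnitude", "signed", "pvalue",
                                      "qvalue", "overlap"),
                     threshold = NULL) {
  kind <- match.arg(kind)
  if (kind == "overlap") {
    if (any(is.na(values))) abort("NA overlap flag at tested id")
    return(ifelse(as.logical(values), "#A020F0", "#000000"))
  }
  if (any(!is.finite(values))) abort("non-finite value at tested id")
  ramp <- function(anchors, t) {
    m <- grDevices::colorRamp(anchors)(pmin(pmax(t, 0), 1))
    grDevices::rgb(m[, 1], m[, 2], m[, 3], maxColorValue = 255)
  }
  if (kind == "magnitude") {
    rng <- range(values)
    t <- if (diff(rng) == 0) rep(0.5, length(values))
      else (values - rng[1]) / diff(rng)
    return(ramp(c("#2166AC", "#FFEE99", "#B2182B"), t))
  }
  if (kind == "signed") {
    mx <- max(abs(values))
    t <- if (mx == 0) rep(0.5, length(values)) else (values / mx + 1) / 2
    return(ramp(c("#2166AC", "#FFFFE0", "#B2182B"), t))
  }
  threshold <- threshold %||% if (kind == "pvalue") 0.01 else 0.005
  if (threshold <= 0 || threshold > 1) abort("threshold must be in (0, 1]")
  sig <- values < threshold
  out <- character(length(values))
  if (any(sig))
    out[sig] <- ramp(c("#CC0000", "#00A000"), values[sig] / threshold)
  if (any(!sig))
    out[!sig] <- ramp(c("#FFE000", "#2166AC"),
                      (values[!sig] - threshold) / (1 - threshold))
  out
}

#' Render a coloured model as a PLY point cloud
#'
#' Writes an ASCII PLY file with per-vertex colours (coordinates in
#' micrometres, never rescaled); output is byte-deterministic for equal
#' inputs. Colours may be given as a vector aligned with the model's valid
#' points or as a data frame `id, colour` which is matched by id.
#'
#' @param model a cast or mean model.
#' @param colours character hex colours, or a data frame `id, colour`.
#' @param path output `.ply` path.
#' @return `path`, invisibly.
#' @export
render_model <- function(model, colours, path) {
  model <- as_cast_df(model, "model")
  vp <- valid_points(model)
  if (is.data.frame(colours)) {
    if (!all(c("id", "colour") %in% names(colours)))
      abort("colour table needs columns id, colour")
    pos <- match(vp$id, colours$id)
    if (any(is.na(pos))) abort("colour ids do not match model ids")
    cols <- colours$colour[pos]
  } else {
    if (length(colours) != nrow(vp))
      abort("colour ids do not match model ids")
    cols <- colours
  }
  rgbm <- t(grDevices::col2rgb(cols))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(vp)),
               "property float x", "property float y", "property float z",
               "property uchar red", "property uchar green",
               "property uchar blue", "end_header",
               sprintf("%.6f %.6f %.6f %d %d %d", vp$x, vp$y, vp$z,
                       rgbm[, 1], rgbm[, 2], rgbm[, 3])), con)
  invisible(path)
}

#' Heat-map style 2D projection plots
#'
#' Orthographic projection along the z (wrap) axis: the antero-posterior
#' axis (y) runs horizontally and the dorso-ventral axis (x) vertically,
#' each point coloured by the chosen field. These are the plot analogues of
#' the PLY exports.
#'
#' @param object a `displacement_field`, `pointwise_tests` or
#'   `overlap_result`.
#' @param field which column to display (displacement fields only).
#' @param model cast/model supplying point positions when `object` carries
#'   none (tests/overlap).
#' @param threshold threshold for p/q colouring.
#' @param ... unused.
#' @return A ggplot object.
#' @name plot_fields
NULL

proj_base <- function() {
  list(ggplot2::coord_equal(),
       ggplot2::labs(x = "antero-posterior y [\u00b5m]",
                     y = "dorso-ventral x [\u00b5m]"),
       ggplot2::theme_minimal())
}

#' @rdname plot_fields
#' @export
autoplot.displacement_field <- function(object,
                                        field = c("magnitude", "dx", "dy",
                                                  "dz"), ...) {
  field <- match.arg(field)
  kind <- if (field == "magnitude") "magnitude" else "signed"
  df <- tibble(py = object$y, px = object$x,
               col = colorize(object[[field]], kind))
  ggplot2::ggplot(df, ggplot2::aes(.data$py, .data$px)) +
    ggplot2::geom_point(colour = df$col, size = 0.4) +
    proj_base() +
    ggplot2::ggtitle(sprintf("displacement %s", field))
}

#' @rdname plot_fields
#' @export
autoplot.overlap_result <- function(object, model, ...) {
  model <- as_cast_df(model, "model")
  pos <- match(object$id, model$id)
  if (any(is.na(pos))) abort("overlap ids missing from model")
  df <- tibble(py = model$y[pos], px = model$x[pos],
               col = colorize(object$overlap, "overlap"))
  ggplot2::ggplot(df, ggplot2::aes(.data$py, .data$px)) +
    ggplot2::geom_point(colour = df$col, size = 0.4) +
    proj_base() +
    ggplot2::ggtitle("confidence-ellipsoid overlap (purple) / difference (black)")
}

#' @rdname plot_fields
#' @export
autoplot.pointwise_tests <- function(object, model,
                                     field = c("p", "q"), threshold = NULL,
                                     ...) {
  field <- match.arg(field)
  if (!field %in% names(object)) abort(sprintf("no %s column", field))
  model <- as_cast_df(model, "model")
  pos <- match(object$id, model$id)
  df <- tibble(py = model$y[pos], px = model$x[pos], axis = object$axis,
               col = colorize(object[[field]],
                              if (field == "p") "pvalue" else "qvalue",
                              threshold))
  ggplot2::ggplot(df, ggplot2::aes(.data$py, .data$px)) +
    ggplot2::geom_point(colour = df$col, size = 0.3) +
    ggplot2::facet_wrap(~axis, ncol = 1) +
    proj_base() +
    ggplot2::ggtitle(sprintf("point-wise %s-value fields", field))
}
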