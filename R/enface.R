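#' En-face maximum-attenuation map
#'
#' Collapses an attenuation volume to a longitudinal (frame x angle) map by
#' taking, for each valid A-line, the maximum attenuation coefficient over
#' the wall span from the lumen border to the internal elastic lamina
#' (inclusive at both ends). Where the IEL is not visible (typically behind
#' a lipid pool) the span extends a fixed fallback depth below the lumen.
#' Finite map values lie in the display range 0-12 1/mm; A-lines that are
#' invalid or have no finite estimate in their span carry `NA`.
#'
#' Sub-sample contour positions are floored at the span start and ceiled at
#' the span end, so a boundary sample is always included.
#'
#' @param volume An [attenuation_volume()].
#' @param contours A [wall_contours()] on the same grid.
#' @param depth_fallback Span depth in mm below the lumen used when the IEL
#'   is absent; default 1 mm.
#' @return An object of class `enface_map` with a `(frame, aline)` matrix
#'   `values`, the geometry, and `depth_fallback`.
#' @export
build_enface <- function(volume, contours, depth_fallback = 1) {
  stopifnot(inherits(volume, "attenuation_volume"),
            inherits(contours, "wall_contours"),
            depth_fallback > 0)
  d <- dim(volume$mu)
  stopifnot(identical(dim(contours$lumen), d[1:2]))
  geom <- volume$geometry
  fallback_samples <- depth_fallback / geom$axial_pitch
  values <- matrix(NA_real_, d[1], d[2])
  for (f in seq_len(d[1])) {
    for (a in seq_len(d[2])) {
      if (!contours$valid[f, a]) next
      lo <- floor(contours$lumen[f, a])
      hi <- if (!is.na(contours$iel[f, a])) ceiling(contours$iel[f, a])
            else ceiling(lo + fallback_samples)
      hi <- min(hi, d[3] - 1)
      if (is.na(lo) || lo > hi) next
      span <- volume$mu[f, a, (lo + 1L):(hi + 1L)]
      if (any(is.finite(span))) values[f, a] <- max(span, na.rm = TRUE)
    }
  }
  structure(list(values = values, geometry = geom,
                 depth_fallback = as.numeric(depth_fallback)),
            class = "enface_map")
}

#' Construct an en-face map from a (frame, aline) matrix
#'
#' @param values Numeric matrix of maximum attenuation per A-line, 1/mm;
#'   `NA` marks invalid A-lines.
#' @param geometry An [oct_geometry()]; defaults to a geometry matching the
#'   matrix width.
#' @param depth_fallback Fallback depth bookkeeping, mm.
#' @return An `enface_map`.
#' @export
enface_map <- function(values, geometry = NULL, depth_fallback = 1) {
  stopifnot(is.matrix(values))
  if (is.null(geometry)) {
    geometry <- oct_geometry(n_alines = ncol(values))
  }
  stopifnot(ncol(values) == geometry$n_alines)
  structure(list(values = values, geometry = geometry,
                 depth_fallback = as.numeric(depth_fallback)),
            class = "enface_map")
}

#' @export
print.enface_map <- function(x, ...) {
  cat("<enface_map> ", nrow(x$values), " frames x ", ncol(x$values),
      " A-lines; ", sum(is.finite(x$values)), " valid entries; range ",
      paste(signif(range(x$values, na.rm = TRUE), 3), collapse = "-"),
      " mm^-1\n", sep = "")
  invisible(x)
}

#' Tidy view of an en-face map
#'
#' @param x An `enface_map`.
#' @param ... Unused.
#' @return Tibble with `frame`, `aline`, `angle_deg`, `mu_max` (NA where
#'   invalid), one row per map entry.
#' @method as_tibble enface_map
#' @export
as_tibble.enface_map <- function(x, ...) {
  nf <- nrow(x$values); na <- ncol(x$values)
  tibble::tibble(
    frame = rep(0:(nf - 1L), times = na),
    aline = rep(0:(na - 1L), each = nf),
    angle_deg = aline_angle(x$geometry, rep(0:(na - 1L), each = nf)),
    mu_max = as.vector(x$values)
  ) |>
    dplyr::arrange(.data$frame, .data$aline)
}

#' Write / read an en-face map as a float TIFF
#'
#' Single-page float TIFF (rows = A-lines, columns = frames) with a JSON
#' sidecar; invalid entries stored as NaN.
#'
#' @param map An `enface_map`.
#' @param path TIFF path.
#' @return `write_enface()` returns `path` invisibly; `read_enface()` an
#'   `enface_map`.
#' @export
write_enface <- function(map, path) {
  stopifnot(inherits(map, "enface_map"))
  m <- t(map$values)
  m[!is.finite(m)] <- NaN
  write_float_tiff(list(m / 16), path)
  g <- map$geometry
  jsonlite::write_json(
    list(units = "mm^-1", sentinel = "NaN", scale_factor = 16,
         depth_fallback_mm = map$depth_fallback,
         axial_pitch_mm = g$axial_pitch, n_alines = g$n_alines,
         frame_pitch_mm = g$frame_pitch,
         catheter_offset_mm = g$catheter_offset),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_enface
#' @export
read_enface <- function(path) {
  sc <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  m <- t(read_float_tiff(path)[1, , ]) * sc$scale_factor
  m[!is.finite(m)] <- NA_real_
  enface_map(m,
             oct_geometry(sc$axial_pitch_mm, sc$n_alines, sc$frame_pitch_mm,
                          sc$catheter_offset_mm),
             depth_fallback = sc$depth_fallback_mm)
}

#' Plot an en-face attenuation map
#'
#' Frames run left to right, rotation angle bottom to top; the colour scale
#' is fixed to 0-12 1/mm and invalid A-lines are drawn in grey.
#'
#' @param object An `enface_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enface_map
#' @export
autoplot.enface_map <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$angle_deg,
                                   fill = .data$mu_max)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(
      option = "inferno", limits = c(0, 12), na.value = "grey70",
      name = expression(mu[t] ~ (mm^-1))) +
    ggplot2::labs(x = "frame", y = "angle (deg)") +
    ggplot2::theme_minimal()
}

#' Render an en-face map to a PNG file
#'
#' @param map An `enface_map`.
#' @param path Output PNG path.
#' @param width,height Device size in pixels.
#' @return `path`, invisibly.
#' @export
render_enface <- function(map, path, width = 800, height = 400) {
  p <- autoplot(map)
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  print(p)
  invisible(path)
}
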