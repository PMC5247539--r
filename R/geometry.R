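#' Acquisition geometry of a polar OCT pullback
#'
#' Describes how array indices map to physical coordinates: the axial pixel
#' pitch along an A-line, the number of A-lines per rotation (frame), the
#' longitudinal distance between frames, and the radial offset of the first
#' axial sample from the coordinate origin (the catheter axis).
#'
#' Radial distance of axial sample `s` (0-based) is
#' `r = catheter_offset + s * axial_pitch` (mm). A-line `a` (0-based) maps to
#' angle `a * 360 / n_alines` degrees.
#'
#' @param axial_pitch Length per axial sample, mm. Must be positive.
#' @param n_alines A-lines per frame. Must be at least 4.
#' @param frame_pitch Longitudinal distance between frames, mm. The clinical
#'   pullbacks this mirrors use 0.2 mm.
#' @param catheter_offset Radial distance from the origin to the first axial
#'   sample, mm. Non-negative.
#' @return An object of class `oct_geometry`.
#' @examples
#' geom <- oct_geometry(axial_pitch = 0.005, n_alines = 504, frame_pitch = 0.2)
#' radial_distance(geom, 0:3)
#' @export
oct_geometry <- function(axial_pitch = 0.005, n_alines = 504L,
                         frame_pitch = 0.2, catheter_offset = 0.5) {
  stopifnot(
    is.numeric(axial_pitch), length(axial_pitch) == 1L, axial_pitch > 0,
    is.numeric(n_alines), length(n_alines) == 1L, n_alines >= 4,
    n_alines == as.integer(n_alines),
    is.numeric(frame_pitch), length(frame_pitch) == 1L, frame_pitch > 0,
    is.numeric(catheter_offset), length(catheter_offset) == 1L,
    catheter_offset >= 0
  )
  structure(
    list(
      axial_pitch = as.numeric(axial_pitch),
      n_alines = as.integer(n_alines),
      frame_pitch = as.numeric(frame_pitch),
      catheter_offset = as.numeric(catheter_offset)
    ),
    class = "oct_geometry"
  )
}

#' Radial distance of axial samples
#'
#' @param geometry An [oct_geometry()].
#' @param samples 0-based axial sample indices (sub-sample values allowed).
#' @return Radial distances in mm.
#' @export
radial_distance <- function(geometry, samples) {
  stopifnot(inherits(geometry, "oct_geometry"))
  geometry$catheter_offset + samples * geometry$axial_pitch
}

#' Angle of A-lines
#'
#' @param geometry An [oct_geometry()].
#' @param alines 0-based A-line indices.
#' @return Angles in degrees in `[0, 360)`.
#' @export
aline_angle <- function(geometry, alines) {
  stopifnot(inherits(geometry, "oct_geometry"))
  (alines %% geometry$n_alines) * (360 / geometry$n_alines)
}

#' @export
print.oct_geometry <- function(x, ...) {
  cat("<oct_geometry> axial pitch ", x$axial_pitch * 1e3, " um, ",
      x$n_alines, " A-lines/frame, frame pitch ", x$frame_pitch * 1e3,
      " um, catheter offset ", x$catheter_offset, " mm\n", sep = "")
  invisible(x)
}
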