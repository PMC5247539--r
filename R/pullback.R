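#' Polar-coordinate OCT pullback
#'
#' The raw input to the attenuation analysis: a 3-D stack of linear OCT
#' intensities indexed `(frame, aline, sample)` together with the acquisition
#' geometry and the system noise floor. Intensities are stored in LINEAR
#' units internally; logarithmic (dB) data are converted on read.
#'
#' @param intensity 3-D non-negative numeric array, dims
#'   `(n_frames, n_alines, n_samples)`.
#' @param geometry An [oct_geometry()]; `n_alines` must match `dim(intensity)[2]`.
#' @param noise_floor Scalar intensity level of the detection noise floor,
#'   same linear units as `intensity`.
#' @return An object of class `oct_pullback`.
#' @export
oct_pullback <- function(intensity, geometry, noise_floor = 0) {
  stopifnot(is.array(intensity), length(dim(intensity)) == 3L)
  if (!inherits(geometry, "oct_geometry")) {
    stop("`geometry` must be an oct_geometry object", call. = FALSE)
  }
  if (dim(intensity)[2] != geometry$n_alines) {
    stop("intensity stack has ", dim(intensity)[2],
         " A-lines but geometry declares ", geometry$n_alines, call. = FALSE)
  }
  if (anyNA(intensity) || any(intensity < 0)) {
    stop("intensities must be non-negative and finite", call. = FALSE)
  }
  stopifnot(is.numeric(noise_floor), length(noise_floor) == 1L,
            noise_floor >= 0)
  structure(
    list(intensity = intensity, geometry = geometry,
         noise_floor = as.numeric(noise_floor)),
    class = "oct_pullback"
  )
}

#' @export
print.oct_pullback <- function(x, ...) {
  d <- dim(x$intensity)
  cat("<oct_pullback> ", d[1], " frames x ", d[2], " A-lines x ", d[3],
      " samples; noise floor ", signif(x$noise_floor, 4), "\n", sep = "")
  print(x$geometry)
  invisible(x)
}

#' Number of frames / A-lines / samples of a pullback-shaped object
#' @param x An `oct_pullback`, `attenuation_volume` or `enface_map`.
#' @return Integer count.
#' @export
n_frames <- function(x) {
  d <- if (!is.null(x$intensity)) dim(x$intensity)
       else if (!is.null(x$mu)) dim(x$mu) else dim(x$values)
  d[1]
}

#' @rdname n_frames
#' @export
n_alines <- function(x) {
  d <- if (!is.null(x$intensity)) dim(x$intensity)
       else if (!is.null(x$mu)) dim(x$mu) else dim(x$values)
  d[2]
}

#' @rdname n_frames
#' @export
n_samples <- function(x) {
  d <- if (!is.null(x$intensity)) dim(x$intensity) else dim(x$mu)
  d[3]
}

#' Write / read a pullback as a float TIFF stack with a JSON sidecar
#'
#' Storage is a multi-page 32-bit float TIFF (one page per frame, rows =
#' A-lines, columns = axial samples) plus `<name>.json` holding the
#' acquisition geometry, the noise floor, and the intensity scale. The writer
#' rescales by a power of two into `[0, 1)` (the factor is recorded in the
#' sidecar) so the only loss is the float32 rounding of each sample:
#' reading back recovers every value exactly at float32 precision, and
#' bit-for-bit when the data are float32-representable.
#'
#' @param pullback An [oct_pullback()].
#' @param path Path of the TIFF file; the sidecar is written next to it as
#'   `<path without extension>.json`.
#' @return `write_pullback()` returns `path` invisibly; `read_pullback()`
#'   returns an [oct_pullback()].
#' @export
write_pullback <- function(pullback, path) {
  stopifnot(inherits(pullback, "oct_pullback"))
  mx <- max(pullback$intensity)
  scale <- if (mx > 0) 2^(ceiling(log2(mx)) + 1) else 1
  pages <- lapply(seq_len(n_frames(pullback)), function(f) {
    matrix(pullback$intensity[f, , ] / scale,
           nrow = n_alines(pullback), ncol = n_samples(pullback))
  })
  write_float_tiff(pages, path)
  sidecar <- list(
    axial_pitch_mm = pullback$geometry$axial_pitch,
    n_alines = pullback$geometry$n_alines,
    frame_pitch_mm = pullback$geometry$frame_pitch,
    catheter_offset_mm = pullback$geometry$catheter_offset,
    intensity_scale = "linear",
    scale_factor = scale,
    noise_floor = pullback$noise_floor
  )
  jsonlite::write_json(sidecar, sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pullback
#' @export
read_pullback <- function(path) {
  sc_path <- sidecar_path(path)
  if (!file.exists(sc_path)) {
    stop("missing JSON sidecar: ", sc_path, call. = FALSE)
  }
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  required <- c("axial_pitch_mm", "n_alines", "frame_pitch_mm",
                "intensity_scale", "noise_floor")
  missing <- setdiff(required, names(sc))
  if (length(missing)) {
    stop("sidecar lacks required keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nf <- length(pages)
  na <- nrow(pages[[1]])
  ns <- ncol(pages[[1]])
  if (na != sc$n_alines) {
    stop("stack has ", na, " A-lines per frame but sidecar declares ",
         sc$n_alines, call. = FALSE)
  }
  scale <- if (!is.null(sc$scale_factor)) sc$scale_factor else 1
  intensity <- array(0, dim = c(nf, na, ns))
  for (f in seq_len(nf)) intensity[f, , ] <- pages[[f]] * scale
  noise_floor <- sc$noise_floor
  if (identical(sc$intensity_scale, "dB")) {
    intensity <- 10^(intensity / 10)
    noise_floor <- 10^(noise_floor / 10)
  } else if (!identical(sc$intensity_scale, "linear")) {
    stop("unknown intensity_scale: ", sc$intensity_scale, call. = FALSE)
  }
  geometry <- oct_geometry(
    axial_pitch = sc$axial_pitch_mm,
    n_alines = sc$n_alines,
    frame_pitch = sc$frame_pitch_mm,
    catheter_offset = if (!is.null(sc$catheter_offset_mm))
      sc$catheter_offset_mm else 0
  )
  oct_pullback(intensity, geometry, noise_floor)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}
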