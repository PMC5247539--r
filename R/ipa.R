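#' Default threshold grid for the IPA family
#'
#' The attenuation thresholds at which the IPA is evaluated:
#' 1, 1.5, 2, ..., 12 1/mm (23 values; the display maximum is 12 1/mm).
#'
#' @param from,to,by Grid limits and step, 1/mm.
#' @return Strictly increasing numeric vector of thresholds.
#' @export
threshold_grid <- function(from = 1, to = 12, by = 0.5) {
  g <- seq(from, to, by = by)
  stopifnot(length(g) >= 1L, !is.unsorted(g, strictly = TRUE), max(g) <= 12)
  g
}

#' Index of Plaque Attenuation over a frame range
#'
#' `IPA_x = 1000 * N(mu_t > x) / N_total`, where the counts run over the
#' valid pixels of the en-face map inside the segment's frame range. The
#' inequality is strict: pixels exactly at the threshold do not count.
#' Invalid pixels (guide-wire shadow, no estimate) are excluded from both
#' numerator and denominator.
#'
#' @param map An [enface_map()].
#' @param segment One-row data frame with `segment_id`, `frame_start`,
#'   `frame_end` (half-open, 0-based), or `NULL` for the whole map.
#' @param x Attenuation threshold, 1/mm.
#' @return One-row tibble: `segment_id`, `threshold`, `ipa` in `[0, 1000]`,
#'   `n_above`, `n_total`. Zero valid pixels is an error (undefined IPA).
#' @examples
#' m <- enface_map(matrix(c(9, 9, 3, 3), 1, 4),
#'                 oct_geometry(n_alines = 4))
#' compute_ipa(m, x = 8.5)
#' @export
compute_ipa <- function(map, segment = NULL, x = 8.5) {
  stopifnot(inherits(map, "enface_map"), is.numeric(x), length(x) == 1L)
  if (is.null(segment)) {
    segment <- tibble::tibble(segment_id = "all", frame_start = 0L,
                              frame_end = nrow(map$values))
  }
  stopifnot(nrow(segment) == 1L,
            segment$frame_start >= 0,
            segment$frame_end <= nrow(map$values),
            segment$frame_start < segment$frame_end)
  vals <- map$values[(segment$frame_start + 1L):segment$frame_end, ,
                     drop = FALSE]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) {
    stop("IPA undefined: no valid pixels in segment ", segment$segment_id,
         call. = FALSE)
  }
  n_above <- sum(vals > x)
  tibble::tibble(
    segment_id = as.character(segment$segment_id),
    threshold = x,
    ipa = 1000 * n_above / length(vals),
    n_above = n_above,
    n_total = length(vals)
  )
}

#' IPA in non-overlapping longitudinal windows
#'
#' Tiles the map with fixed-length windows from frame 0 (window length in
#' frames = `round(window_mm / frame_pitch)`; 4 mm at a 0.2 mm frame pitch
#' gives 20 frames), drops the trailing partial window, and scores each tile
#' with [compute_ipa()]. Windows without valid pixels are reported with
#' `NA` IPA rather than failing.
#'
#' @param map An [enface_map()].
#' @param window_mm Window length, mm; at least one frame pitch.
#' @param x Attenuation threshold, 1/mm.
#' @return Tibble with one row per window: `frame_start`, `frame_end`,
#'   `threshold`, `ipa`, `n_above`, `n_total`.
#' @export
ipa_windows <- function(map, window_mm = 4, x = 8.5) {
  stopifnot(inherits(map, "enface_map"),
            window_mm >= map$geometry$frame_pitch)
  wl <- as.integer(round(window_mm / map$geometry$frame_pitch))
  nf <- nrow(map$values)
  if (nf < wl) {
    return(tibble::tibble(frame_start = integer(), frame_end = integer(),
                          threshold = numeric(), ipa = numeric(),
                          n_above = integer(), n_total = integer()))
  }
  starts <- seq(0L, nf - wl, by = wl)
  purrr::map_dfr(starts, function(s) {
    seg <- tibble::tibble(segment_id = sprintf("win_%04d", s),
                          frame_start = s, frame_end = s + wl)
    res <- tryCatch(compute_ipa(map, seg, x), error = function(e) NULL)
    if (is.null(res)) {
      res <- tibble::tibble(segment_id = seg$segment_id, threshold = x,
                            ipa = NA_real_, n_above = NA_integer_,
                            n_total = 0L)
    }
    dplyr::bind_cols(tibble::tibble(frame_start = s, frame_end = s + wl),
                     res[-1L])
  })
}

#' IPA family over a threshold grid
#'
#' Evaluates [compute_ipa()] at every threshold of the grid; all thresholds
#' share the segment's valid-pixel census, so the family is non-increasing
#' in the threshold.
#'
#' @param map An [enface_map()].
#' @param segment One-row segment data frame (see [compute_ipa()]) or
#'   `NULL` for the whole map.
#' @param grid Thresholds, 1/mm; default [threshold_grid()].
#' @return Tibble with one row per threshold.
#' @export
ipa_family <- function(map, segment = NULL, grid = threshold_grid()) {
  purrr::map_dfr(grid, function(x) compute_ipa(map, segment, x))
}
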