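#' Vessel-wall contours for a pullback
#'
#' Per-frame, per-A-line radial positions (0-based axial sample indices,
#' sub-sample precision allowed) of the lumen border and the internal elastic
#' lamina (IEL), plus a validity mask. Invalid A-lines (guide-wire shadow,
#' artifacts) are excluded from fitting and mapping. An absent IEL (invisible
#' behind lipid) is encoded as `NA`; downstream the en-face sampling span then
#' falls back to a fixed depth below the lumen.
#'
#' @param lumen Numeric matrix `(frame, aline)` of lumen sample indices.
#' @param iel Numeric matrix, same shape; `NA` where the IEL is absent.
#' @param valid Logical matrix, same shape; `FALSE` marks unusable A-lines.
#' @param n_samples Axial samples per A-line, used to validate indices
#'   (optional; skip check when `NULL`).
#' @return An object of class `wall_contours`.
#' @export
wall_contours <- function(lumen, iel = NULL, valid = NULL, n_samples = NULL) {
  stopifnot(is.matrix(lumen))
  if (is.null(iel)) iel <- matrix(NA_real_, nrow(lumen), ncol(lumen))
  if (is.null(valid)) valid <- matrix(TRUE, nrow(lumen), ncol(lumen))
  stopifnot(identical(dim(lumen), dim(iel)),
            identical(dim(lumen), dim(valid)), is.logical(valid))
  bad <- valid & (is.na(lumen) | lumen < 0)
  if (any(bad)) {
    stop("valid A-lines must have lumen index >= 0; first offender (frame, aline) = (",
         paste(which(bad, arr.ind = TRUE)[1, ] - 1L, collapse = ", "), ")",
         call. = FALSE)
  }
  bad <- valid & !is.na(iel) & (iel <= lumen)
  if (any(bad)) {
    off <- which(bad, arr.ind = TRUE)
    stop("lumen index must lie strictly inside the IEL; offending (frame, aline): ",
         paste(apply(off - 1L, 1L, function(z) paste0("(", z[1], ", ", z[2], ")")),
               collapse = " "),
         call. = FALSE)
  }
  if (!is.null(n_samples)) {
    bad <- valid & ((!is.na(iel) & iel >= n_samples) | lumen >= n_samples)
    if (any(bad)) stop("contour indices exceed the axial sample count",
                       call. = FALSE)
  }
  structure(list(lumen = lumen, iel = iel, valid = valid),
            class = "wall_contours")
}

#' @export
print.wall_contours <- function(x, ...) {
  cat("<wall_contours> ", nrow(x$lumen), " frames x ", ncol(x$lumen),
      " A-lines; ", sum(x$valid), " valid A-lines, ",
      sum(x$valid & is.na(x$iel)), " with absent IEL\n", sep = "")
  invisible(x)
}

#' Read / write wall contours as CSV
#'
#' The on-disk form is a long table with columns
#' `frame, aline, lumen_idx, iel_idx, valid` (0-based indices; `iel_idx`
#' empty when the IEL is not visible). A-lines absent from the file default
#' to `valid = FALSE`.
#'
#' @param path CSV file path.
#' @param pullback The [oct_pullback()] the contours belong to (fixes the
#'   grid dimensions and validates indices).
#' @param contours A [wall_contours()] object (for writing).
#' @return `read_contours()` returns a [wall_contours()];
#'   `write_contours()` returns `path` invisibly.
#' @export
read_contours <- function(path, pullback) {
  stopifnot(inherits(pullback, "oct_pullback"))
  df <- readr::read_csv(path, col_types = readr::cols(
    frame = readr::col_integer(),
    aline = readr::col_integer(),
    lumen_idx = readr::col_double(),
    iel_idx = readr::col_double(),
    valid = readr::col_logical()
  ))
  contours_from_table(df, n_frames(pullback), n_alines(pullback),
                      n_samples(pullback))
}

#' Build wall contours from a long table
#'
#' @param df Data frame with columns `frame, aline, lumen_idx, iel_idx, valid`.
#' @param n_frames,n_alines Grid dimensions.
#' @param n_samples Axial sample count used for index validation (optional).
#' @return A [wall_contours()].
#' @export
contours_from_table <- function(df, n_frames, n_alines, n_samples = NULL) {
  need <- c("frame", "aline", "lumen_idx", "iel_idx", "valid")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("contour table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$frame < 0 | df$frame >= n_frames |
          df$aline < 0 | df$aline >= n_alines)) {
    stop("contour rows outside the pullback grid", call. = FALSE)
  }
  lumen <- matrix(NA_real_, n_frames, n_alines)
  iel <- matrix(NA_real_, n_frames, n_alines)
  valid <- matrix(FALSE, n_frames, n_alines)
  idx <- cbind(df$frame + 1L, df$aline + 1L)
  lumen[idx] <- df$lumen_idx
  iel[idx] <- df$iel_idx
  valid[idx] <- df$valid
  wall_contours(lumen, iel, valid, n_samples = n_samples)
}

#' @rdname read_contours
#' @export
write_contours <- function(contours, path) {
  stopifnot(inherits(contours, "wall_contours"))
  df <- as_tibble(contours)
  readr::write_csv(df, path, na = "")
  invisible(path)
}

#' Tidy view of wall contours
#'
#' @param x A [wall_contours()].
#' @param ... Unused.
#' @return A tibble with one row per (frame, aline) and columns
#'   `frame, aline, lumen_idx, iel_idx, valid` (0-based).
#' @method as_tibble wall_contours
#' @export
as_tibble.wall_contours <- function(x, ...) {
  nf <- nrow(x$lumen); na <- ncol(x$lumen)
  tibble::tibble(
    frame = rep(0:(nf - 1L), times = na),
    aline = rep(0:(na - 1L), each = nf),
    lumen_idx = as.vector(x$lumen),
    iel_idx = as.vector(x$iel),
    valid = as.vector(x$valid)
  ) |>
    dplyr::arrange(.data$frame, .data$aline)
}

#' Plaque segments table
#'
#' Segments are half-open frame ranges `[frame_start, frame_end)` (0-based)
#' labelled by `segment_id`; their longitudinal span in mm is
#' `(frame_end - frame_start) * frame_pitch`.
#'
#' @param df Data frame with columns `segment_id, frame_start, frame_end`.
#' @param n_frames Optional frame count for bounds checking.
#' @return A validated tibble of segments.
#' @export
plaque_segments <- function(df, n_frames = NULL) {
  need <- c("segment_id", "frame_start", "frame_end")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("segment table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(df[need])
  bad <- out$frame_start < 0 | out$frame_start >= out$frame_end
  if (!is.null(n_frames)) bad <- bad | out$frame_end > n_frames
  if (any(bad)) {
    stop("invalid segment ranges for: ",
         paste(out$segment_id[bad], collapse = ", "), call. = FALSE)
  }
  out
}

#' @rdname plaque_segments
#' @param path CSV with columns `segment_id,frame_start,frame_end`.
#' @export
read_segments <- function(path, n_frames = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols(
    segment_id = readr::col_character(),
    frame_start = readr::col_integer(),
    frame_end = readr::col_integer()
  ))
  plaque_segments(df, n_frames)
}
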