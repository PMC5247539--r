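#' Lipid score from per-frame lipid arcs
#'
#' Manual OCT lipid reads give, per frame of a plaque segment, the angular
#' arc (degrees) subtended by the lipid core; an arc of 0 means no lipid in
#' that frame. The segment's lipid length is the number of lipid-containing
#' frames times the frame pitch; the mean arc is averaged over
#' lipid-containing frames only (configurable); and the lipid score is their
#' product in mm*degrees. A segment with no lipid frame scores 0.
#'
#' @param arcs Data frame with columns `segment_id`, `frame`, `arc_deg`
#'   (0-360; one row per frame). Multiple segments allowed.
#' @param frame_pitch Longitudinal frame spacing, mm.
#' @param mean_over Either `"lipid_frames"` (default: average the arc over
#'   frames with `arc_deg > 0`) or `"all_frames"`.
#' @return Tibble with one row per segment: `segment_id`, `mean_arc`
#'   (degrees), `lipid_length` (mm), `score` (mm*degrees).
#' @examples
#' arcs <- tibble::tibble(segment_id = "p1", frame = 0:4,
#'                        arc_deg = c(0, 90, 110, 0, 0))
#' lipid_score(arcs, frame_pitch = 0.2)
#' @export
lipid_score <- function(arcs, frame_pitch = 0.2,
                        mean_over = c("lipid_frames", "all_frames")) {
  mean_over <- match.arg(mean_over)
  need <- c("segment_id", "frame", "arc_deg")
  missing <- setdiff(need, names(arcs))
  if (length(missing)) {
    stop("arc table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(arcs$arc_deg < 0 | arcs$arc_deg > 360)) {
    stop("lipid arcs must lie in [0, 360] degrees", call. = FALSE)
  }
  stopifnot(frame_pitch > 0)
  arcs |>
    dplyr::group_by(.data$segment_id) |>
    dplyr::summarise(
      mean_arc = if (any(.data$arc_deg > 0)) {
        if (mean_over == "lipid_frames") mean(.data$arc_deg[.data$arc_deg > 0])
        else mean(.data$arc_deg)
      } else 0,
      lipid_length = sum(.data$arc_deg > 0) * frame_pitch,
      .groups = "drop"
    ) |>
    dplyr::mutate(score = .data$mean_arc * .data$lipid_length)
}

#' Pearson product-moment correlation
#'
#' @param xs,ys Equal-length numeric vectors (length at least 3), each with
#'   nonzero variance.
#' @return The correlation coefficient in `[-1, 1]`. Zero variance in
#'   either vector is an error (undefined correlation).
#' @export
pearson <- function(xs, ys) {
  stopifnot(length(xs) == length(ys), length(xs) >= 3L,
            all(is.finite(xs)), all(is.finite(ys)))
  if (stats::var(xs) == 0 || stats::var(ys) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  stats::cor(xs, ys, method = "pearson")
}

#' Threshold sweep of IPA against the lipid score
#'
#' For each attenuation threshold x of the grid, correlates the segments'
#' `IPA_x` with their manual lipid scores (Pearson's r); picks the
#' threshold with the highest r (ties to the lowest threshold, the more
#' sensitive detector) and fits the least-squares line of score on IPA at
#' that threshold. Thresholds at which the IPA vector has zero variance are
#' skipped and flagged.
#'
#' @param scores Tibble from [lipid_score()] (columns `segment_id`,
#'   `score`), one row per segment; at least 3 segments.
#' @param ipa_results Tibble of per-segment IPA families (columns
#'   `segment_id`, `threshold`, `ipa`) covering the same segments, e.g.
#'   rows of [ipa_family()] bound together.
#' @return An object of class `ipa_sweep`; see [tidy.ipa_sweep()] and
#'   [glance.ipa_sweep()]. Fewer than 3 usable thresholds is an error.
#' @export
sweep_thresholds <- function(scores, ipa_results) {
  stopifnot(all(c("segment_id", "score") %in% names(scores)),
            all(c("segment_id", "threshold", "ipa") %in% names(ipa_results)))
  if (nrow(scores) < 3L) stop("need at least 3 segments", call. = FALSE)
  if (anyDuplicated(scores$segment_id)) {
    stop("duplicate segment ids in scores", call. = FALSE)
  }
  joined <- dplyr::inner_join(ipa_results,
                              scores[c("segment_id", "score")],
                              by = "segment_id")
  if (!setequal(unique(joined$segment_id), scores$segment_id)) {
    stop("IPA results and scores cover different segment sets",
         call. = FALSE)
  }
  per_thr <- joined |>
    dplyr::group_by(.data$threshold) |>
    dplyr::summarise(
      n = dplyr::n(),
      skipped = stats::var(.data$ipa) == 0 || stats::var(.data$score) == 0,
      r = if (skipped) NA_real_ else pearson(.data$ipa, .data$score),
      .groups = "drop"
    ) |>
    dplyr::mutate(r2 = .data$r^2) |>
    dplyr::arrange(.data$threshold)
  usable <- per_thr |> dplyr::filter(!.data$skipped)
  if (nrow(usable) < 3L) {
    stop("sweep failed: fewer than 3 thresholds with usable variance",
         call. = FALSE)
  }
  best <- usable$threshold[which.max(usable$r)]  # which.max: first max,
  best_r <- max(usable$r)                        # i.e. lowest threshold
  at_best <- joined |> dplyr::filter(.data$threshold == best)
  fit <- stats::lm(score ~ ipa, data = at_best)
  n <- nrow(at_best)
  tstat <- best_r * sqrt((n - 2) / (1 - best_r^2))
  p_value <- 2 * stats::pt(-abs(tstat), df = n - 2)
  structure(
    list(per_threshold = per_thr,
         best_threshold = best,
         best_r = best_r,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         p_value = p_value,
         n_segments = n,
         data = at_best),
    class = "ipa_sweep"
  )
}

#' @export
print.ipa_sweep <- function(x, ...) {
  cat("<ipa_sweep> ", x$n_segments, " segments, ",
      nrow(x$per_threshold), " thresholds\n",
      "best threshold x = ", x$best_threshold, " mm^-1: r = ",
      signif(x$best_r, 3), " (r^2 = ", signif(x$best_r^2, 3),
      ", p = ", format.pval(x$p_value, digits = 2), ")\n",
      "score = ", signif(x$intercept, 3), " + ", signif(x$slope, 3),
      " * IPA\n", sep = "")
  invisible(x)
}

#' Per-threshold sweep results
#'
#' @param x An `ipa_sweep`.
#' @param ... Unused.
#' @return Tibble with one row per threshold: `threshold`, `n`, `skipped`,
#'   `r`, `r2`.
#' @method tidy ipa_sweep
#' @export
tidy.ipa_sweep <- function(x, ...) {
  x$per_threshold
}

#' One-row summary of a threshold sweep
#'
#' @param x An `ipa_sweep`.
#' @param ... Unused.
#' @return One-row tibble: `best_threshold`, `best_r`, `r2`, `slope`,
#'   `intercept`, `p_value`, `n_segments`.
#' @method glance ipa_sweep
#' @export
glance.ipa_sweep <- function(x, ...) {
  tibble::tibble(
    best_threshold = x$best_threshold,
    best_r = x$best_r,
    r2 = x$best_r^2,
    slope = x$slope,
    intercept = x$intercept,
    p_value = x$p_value,
    n_segments = x$n_segments
  )
}

#' Plot the threshold sweep
#'
#' Correlation coefficient against the attenuation threshold, with the best
#' threshold marked.
#'
#' @param object An `ipa_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ipa_sweep
#' @export
autoplot.ipa_sweep <- function(object, ...) {
  df <- tidy(object) |> dplyr::filter(!.data$skipped)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$r)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = expression(threshold ~ x ~ (mm^-1)),
                  y = "Pearson r (lipid score vs IPA)") +
    ggplot2::theme_minimal()
}
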