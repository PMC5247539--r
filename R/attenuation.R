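#' Catheter/system model for signal compensation
#'
#' The detected single-scattering OCT signal is
#' `I(r) = T(r) * S(r) * I0 * exp(-mu_t * r)`, where `T(r)` is the confocal
#' point-spread function of the catheter optics and `S(r)` the system
#' sensitivity roll-off. Before slope fitting, the measured intensity is
#' divided by `T(r) * S(r)` so that the remaining decay is governed by the
#' tissue attenuation coefficient `mu_t` alone.
#'
#' `T(r)` is modelled as a Lorentzian confocal gate
#' `1 / (((r - focus_position) / apparent_rayleigh_length)^2 + 1)` and
#' `S(r)` as a Gaussian fall-off `exp(-(r / rolloff_length)^2)`; set
#' `rolloff_length = NA` for a system with negligible roll-off (`S == 1`).
#' The source intensity `I0` is always a free per-window fit parameter.
#'
#' @param focus_position Distance of the beam focus from the coordinate
#'   origin, mm.
#' @param apparent_rayleigh_length Confocal depth parameter, mm; positive.
#' @param rolloff_length Characteristic depth of the sensitivity roll-off,
#'   mm, or `NA` for none.
#' @return An object of class `system_model`.
#' @examples
#' sys <- system_model(focus_position = 1, apparent_rayleigh_length = 0.5,
#'                     rolloff_length = 4)
#' compensation_curve(sys, c(1, 1.5, 2))
#' @export
system_model <- function(focus_position = 1.2, apparent_rayleigh_length = 0.6,
                         rolloff_length = NA) {
  stopifnot(is.numeric(focus_position), length(focus_position) == 1L,
            is.numeric(apparent_rayleigh_length),
            apparent_rayleigh_length > 0,
            length(rolloff_length) == 1L,
            is.na(rolloff_length) ||
              (is.numeric(rolloff_length) && rolloff_length > 0))
  structure(
    list(focus_position = as.numeric(focus_position),
         apparent_rayleigh_length = as.numeric(apparent_rayleigh_length),
         rolloff_length = as.numeric(rolloff_length)),
    class = "system_model"
  )
}

#' Identity system model (no confocal gating, no roll-off)
#'
#' Convenience model whose compensation curve is identically 1; with it,
#' fitting reduces to a plain log-linear regression of intensity on depth.
#' @return A `system_model` whose [compensation_curve()] is constant 1.
#' @export
identity_system <- function() {
  m <- system_model(focus_position = 0, apparent_rayleigh_length = 1,
                    rolloff_length = NA)
  m$identity <- TRUE
  m
}

#' Compensation factor T(r) * S(r)
#'
#' @param system A [system_model()].
#' @param r_values Radial distances, mm (finite, non-negative).
#' @return Positive factors, same length as `r_values`. Equals 1 at the
#'   focus when there is no roll-off.
#' @export
compensation_curve <- function(system, r_values) {
  stopifnot(inherits(system, "system_model"),
            all(is.finite(r_values)), all(r_values >= 0))
  if (isTRUE(system$identity)) return(rep(1, length(r_values)))
  tt <- 1 / (((r_values - system$focus_position) /
                system$apparent_rayleigh_length)^2 + 1)
  if (!is.na(system$rolloff_length)) {
    tt <- tt * exp(-(r_values / system$rolloff_length)^2)
  }
  tt
}

#' Fitting configuration
#'
#' @param window_lengths Candidate fitting-window lengths in mm, evaluated
#'   longest-first at each window start. Defaults 0.6, 0.4, 0.2 mm.
#' @param min_quality Minimum coefficient of determination (R^2) of the
#'   log-linear fit for a candidate window to be accepted; in `[0, 1]`.
#' @param noise_margin Samples with intensity at or below
#'   `noise_margin * noise_floor` are excluded from fits; `>= 1`.
#' @param clamp_range Reported attenuation coefficients are clamped to this
#'   `[low, high]` range in 1/mm, mirroring the 0-12 1/mm display range.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(window_lengths = c(0.6, 0.4, 0.2), min_quality = 0.6,
                       noise_margin = 2, clamp_range = c(0, 12)) {
  stopifnot(is.numeric(window_lengths), length(window_lengths) >= 1L,
            all(window_lengths > 0),
            is.numeric(min_quality), min_quality >= 0, min_quality <= 1,
            is.numeric(noise_margin), noise_margin >= 1,
            length(clamp_range) == 2L, clamp_range[1] < clamp_range[2])
  structure(
    list(window_lengths = sort(as.numeric(window_lengths), decreasing = TRUE),
         min_quality = as.numeric(min_quality),
         noise_margin = as.numeric(noise_margin),
         clamp_range = as.numeric(clamp_range)),
    class = "fit_config"
  )
}

#' Fit the single-scattering model in one depth window
#'
#' Divides the measured intensities by the compensation curve
#' `T(r) * S(r)`, takes the natural log, and regresses it on depth by
#' ordinary least squares. The attenuation coefficient is the negated
#' slope; the intercept gives the source intensity `I0`. The returned
#' estimate is NOT clamped; clamping happens at volume storage.
#'
#' A perfectly constant compensated segment has zero residual and zero
#' slope; its R^2 (formally 0/0) is reported as 1 by convention.
#'
#' @param intensity_segment Linear intensities, one per sample.
#' @param r_segment Radial distances in mm, strictly increasing.
#' @param system A [system_model()].
#' @return A list with `mu` (1/mm), `i0`, `quality` (R^2), and `n_used`.
#'   When fewer than 3 samples have positive compensated intensity, `mu`,
#'   `i0` and `quality` are `NA` (insufficient data).
#' @export
fit_window <- function(intensity_segment, r_segment,
                       system = identity_system()) {
  stopifnot(length(intensity_segment) == length(r_segment),
            !is.unsorted(r_segment, strictly = TRUE))
  comp <- compensation_curve(system, r_segment)
  z <- intensity_segment / comp
  use <- is.finite(z) & z > 0
  if (sum(use) < 3L) {
    return(list(mu = NA_real_, i0 = NA_real_, quality = NA_real_,
                n_used = sum(use)))
  }
  y <- log(z[use])
  r <- r_segment[use]
  n <- length(r)
  rbar <- mean(r); ybar <- mean(y)
  sxx <- sum((r - rbar)^2)
  sxy <- sum((r - rbar) * (y - ybar))
  syy <- sum((y - ybar)^2)
  slope <- sxy / sxx
  quality <- if (syy <= 0) 1 else (sxy * sxy) / (sxx * syy)
  list(mu = -slope, i0 = exp(ybar - slope * rbar),
       quality = quality, n_used = n)
}

# Rolling OLS of y on r over all windows of `nw` consecutive samples,
# tolerating masked samples (y = NA). Returns per-start slope, intercept,
# R^2 and usable-sample count; starts index the first sample of the window.
# Exact: moment sums are accumulated only over unmasked samples.
rolling_ols <- function(y, r, nw) {
  n <- length(y)
  if (nw > n) {
    return(list(slope = numeric(0), icpt = numeric(0),
                r2 = numeric(0), count = integer(0)))
  }
  m <- as.numeric(is.finite(y))
  y0 <- ifelse(is.finite(y), y, 0)
  roll <- function(v) {
    cs <- cumsum(v)
    cs[nw:n] - c(0, cs[seq_len(n - nw)])
  }
  cnt <- roll(m)
  sr <- roll(m * r)
  srr <- roll(m * r * r)
  sy <- roll(y0)
  syy <- roll(y0 * y0)
  sry <- roll(r * y0)
  cnt1 <- pmax(cnt, 1)
  sxx <- srr - sr * sr / cnt1
  sxy <- sry - sr * sy / cnt1
  # guard tiny negative centered sums from cancellation
  syc <- pmax(syy - sy * sy / cnt1, 0)
  ok <- cnt >= 3 & sxx > 0
  slope <- icpt <- r2 <- rep(NA_real_, length(cnt))
  slope[ok] <- sxy[ok] / sxx[ok]
  r2[ok] <- pmin((sxy[ok] * sxy[ok]) / (sxx[ok] * syc[ok]), 1)
  r2[ok & syc <= 0] <- 1
  icpt[ok] <- (sy[ok] - slope[ok] * sr[ok]) / cnt[ok]
  list(slope = slope, icpt = icpt, r2 = r2, count = cnt)
}

# samples spanning a window of `len` mm at pitch `pitch` mm
window_samples <- function(len, pitch) as.integer(round(len / pitch)) + 1L

#' Fit all depth windows of one A-line
#'
#' Slides fitting windows over the A-line starting at the lumen border. At
#' each window start the candidate window lengths are tried longest-first
#' and the first whose fit quality reaches `min_quality` is kept (falling
#' back to the best-quality candidate). The window's clamped attenuation
#' coefficient is assigned to every sample the window covers; where windows
#' overlap, the higher-quality window wins (ties to the shorter, then the
#' shallower, window). Samples at or below `noise_margin * noise_floor` are
#' excluded from the regressions.
#'
#' @param pullback An [oct_pullback()].
#' @param frame,aline 0-based indices.
#' @param contours A [wall_contours()].
#' @param system A [system_model()].
#' @param config A [fit_config()].
#' @return A list with numeric vectors `mu` and `quality` of length
#'   `n_samples` (`NA` = no estimate). An invalid A-line yields all-`NA`.
#' @export
fit_aline <- function(pullback, frame, aline, contours,
                      system = identity_system(), config = fit_config()) {
  ns <- n_samples(pullback)
  geom <- pullback$geometry
  r <- radial_distance(geom, 0:(ns - 1L))
  comp <- compensation_curve(system, r)
  nws <- pmin(vapply(config$window_lengths, window_samples,
                     integer(1), pitch = geom$axial_pitch), ns)
  fit_aline_core(
    pullback$intensity[frame + 1L, aline + 1L, ], r, comp,
    valid = contours$valid[frame + 1L, aline + 1L],
    lumen = contours$lumen[frame + 1L, aline + 1L],
    noise_level = config$noise_margin * pullback$noise_floor,
    nws = nws, min_quality = config$min_quality,
    clamp = config$clamp_range)
}

# worker shared by fit_aline / fit_pullback; per-pullback invariants
# (r, comp, window sizes) are computed by the caller
fit_aline_core <- function(intensity, r, comp, valid, lumen, noise_level,
                           nws, min_quality, clamp) {
  ns <- length(intensity)
  out <- list(mu = rep(NA_real_, ns), quality = rep(NA_real_, ns))
  ls <- floor(lumen)
  if (!valid || is.na(ls) || ls >= ns - 2L) return(out)
  z <- intensity / comp
  usable <- intensity > noise_level & z > 0
  y <- rep(NA_real_, ns)
  y[usable] <- log(z[usable])
  first <- ls + 1L  # 1-based index of the lumen sample
  fits <- lapply(nws, function(nw) rolling_ols(y, r, nw))

  # candidate selection per start: longest adequate window, else best R^2
  max_start <- ns - min(nws) + 1L  # 1-based
  if (first > max_start) return(out)
  starts <- first:max_start
  k <- length(nws)
  qmat <- matrix(NA_real_, length(starts), k)
  mmat <- matrix(NA_real_, length(starts), k)
  for (j in seq_len(k)) {
    avail <- starts <= ns - nws[j] + 1L
    idx <- starts[avail]
    qmat[avail, j] <- fits[[j]]$r2[idx]
    mmat[avail, j] <- -fits[[j]]$slope[idx]
  }
  adequate <- !is.na(qmat) & qmat >= min_quality
  has_adequate <- rowSums(adequate) > 0L
  any_fit <- rowSums(!is.na(qmat)) > 0L
  qneg <- qmat
  qneg[is.na(qneg)] <- -Inf
  pick <- integer(length(starts))
  pick[any_fit] <- max.col(qneg, ties.method = "first")[any_fit]
  pick[has_adequate] <- max.col(adequate, ties.method = "first")[has_adequate]
  keep <- pick > 0L
  if (!any(keep)) return(out)
  w_start <- starts[keep]
  w_len <- nws[pick[keep]]
  w_q <- qmat[cbind(which(keep), pick[keep])]
  w_mu <- pmin(pmax(mmat[cbind(which(keep), pick[keep])],
                    clamp[1]), clamp[2])

  # overlap resolution: higher quality wins, ties to shorter then shallower
  ord <- order(-w_q, w_len, w_start)
  mu_out <- out$mu
  q_out <- out$quality
  assigned <- rep(FALSE, ns)
  for (i in ord) {
    span <- w_start[i]:(w_start[i] + w_len[i] - 1L)
    new <- span[!assigned[span]]
    if (length(new)) {
      mu_out[new] <- w_mu[i]
      q_out[new] <- w_q[i]
      assigned[new] <- TRUE
    }
  }
  list(mu = mu_out, quality = q_out)
}

#' Per-pixel attenuation estimates for a whole pullback
#'
#' Applies [fit_aline()] to every valid (frame, A-line) pair. The result is
#' deterministic given its inputs; invalid A-lines and unfittable regions
#' carry the no-estimate sentinel (`NA`).
#'
#' @inheritParams fit_aline
#' @return An object of class `attenuation_volume` with 3-D arrays `mu`
#'   (1/mm, clamped to `config$clamp_range`) and `quality` (fit R^2), plus
#'   the acquisition geometry.
#' @export
fit_pullback <- function(pullback, contours, system = identity_system(),
                         config = fit_config()) {
  stopifnot(inherits(pullback, "oct_pullback"),
            inherits(contours, "wall_contours"),
            identical(dim(contours$lumen),
                      dim(pullback$intensity)[1:2]))
  nf <- n_frames(pullback); na <- n_alines(pullback); ns <- n_samples(pullback)
  geom <- pullback$geometry
  r <- radial_distance(geom, 0:(ns - 1L))
  comp <- compensation_curve(system, r)
  nws <- pmin(vapply(config$window_lengths, window_samples,
                     integer(1), pitch = geom$axial_pitch), ns)
  noise_level <- config$noise_margin * pullback$noise_floor
  mu <- array(NA_real_, dim = c(nf, na, ns))
  quality <- array(NA_real_, dim = c(nf, na, ns))
  for (f in seq_len(nf)) {
    for (a in seq_len(na)) {
      if (!contours$valid[f, a]) next
      res <- fit_aline_core(
        pullback$intensity[f, a, ], r, comp, valid = TRUE,
        lumen = contours$lumen[f, a], noise_level = noise_level,
        nws = nws, min_quality = config$min_quality,
        clamp = config$clamp_range)
      mu[f, a, ] <- res$mu
      quality[f, a, ] <- res$quality
    }
  }
  attenuation_volume(mu, quality, pullback$geometry)
}

#' Attenuation volume container
#'
#' @param mu 3-D array `(frame, aline, sample)` of attenuation coefficients
#'   in 1/mm; `NA` = no estimate.
#' @param quality Same-shape array of fit R^2 values.
#' @param geometry The [oct_geometry()] of the source pullback.
#' @return An object of class `attenuation_volume`.
#' @export
attenuation_volume <- function(mu, quality = NULL, geometry = NULL) {
  stopifnot(is.array(mu), length(dim(mu)) == 3L)
  if (is.null(quality)) quality <- array(NA_real_, dim = dim(mu))
  stopifnot(identical(dim(mu), dim(quality)))
  structure(list(mu = mu, quality = quality, geometry = geometry),
            class = "attenuation_volume")
}

#' @export
print.attenuation_volume <- function(x, ...) {
  d <- dim(x$mu)
  est <- sum(is.finite(x$mu))
  cat("<attenuation_volume> ", d[1], " x ", d[2], " x ", d[3], "; ",
      est, " estimated samples (", round(100 * est / length(x$mu), 1),
      "%)\n", sep = "")
  invisible(x)
}

#' Write / read an attenuation volume as a float TIFF stack
#'
#' One page per frame, rows = A-lines, columns = samples; units 1/mm; the
#' no-estimate sentinel is stored as NaN. A JSON sidecar carries the
#' geometry.
#'
#' @param volume An [attenuation_volume()].
#' @param path TIFF path; sidecar goes to `<path without extension>.json`.
#' @return `write_attenuation()` returns `path` invisibly;
#'   `read_attenuation()` an [attenuation_volume()] (quality is not
#'   persisted).
#' @export
write_attenuation <- function(volume, path) {
  stopifnot(inherits(volume, "attenuation_volume"))
  d <- dim(volume$mu)
  pages <- lapply(seq_len(d[1]), function(f) {
    m <- matrix(volume$mu[f, , ], d[2], d[3])
    m[!is.finite(m)] <- NaN
    m / 16  # fixed power-of-two scale keeps values in [0,1) for 0-12 1/mm
  })
  write_float_tiff(pages, path)
  g <- volume$geometry
  jsonlite::write_json(
    list(units = "mm^-1", sentinel = "NaN", scale_factor = 16,
         axial_pitch_mm = g$axial_pitch, n_alines = g$n_alines,
         frame_pitch_mm = g$frame_pitch,
         catheter_offset_mm = g$catheter_offset),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_attenuation
#' @export
read_attenuation <- function(path) {
  sc <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  arr <- read_float_tiff(path) * sc$scale_factor
  arr[!is.finite(arr)] <- NA_real_
  geometry <- oct_geometry(sc$axial_pitch_mm, sc$n_alines, sc$frame_pitch_mm,
                           sc$catheter_offset_mm)
  attenuation_volume(arr, geometry = geometry)
}
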