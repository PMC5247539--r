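#' Synthetic tissue scene
#'
#' Describes a vessel-wall geometry with known optical properties for the
#' forward simulator: a (possibly constant) lumen radius, a wall of given
#' thickness and background attenuation, zero or more plaque regions of
#' elevated attenuation, and an optional guide-wire shadow arc that is
#' masked invalid.
#'
#' @param n_frames Number of frames to simulate.
#' @param lumen_radius Lumen radius in mm; a scalar or a
#'   `(frame, aline)` matrix.
#' @param wall_thickness Radial distance from lumen to the internal elastic
#'   lamina, mm.
#' @param background_mu Attenuation of normal intima, 1/mm (0-12].
#' @param plaques Tibble with columns `frame_start`, `frame_end` (half-open,
#'   0-based), `arc_start_deg`, `arc_extent_deg`, `depth_start_mm`,
#'   `depth_end_mm` (measured from the lumen border), `mu` (1/mm). May have
#'   zero rows.
#' @param guidewire_arc Length-2 numeric `c(start_deg, extent_deg)` of the
#'   guide-wire shadow, or `NULL` for none.
#' @param i0 Source intensity at the lumen border (linear units).
#' @return An object of class `tissue_scene`.
#' @export
tissue_scene <- function(n_frames = 25L, lumen_radius = 1.0,
                         wall_thickness = 0.8, background_mu = 4,
                         plaques = NULL, guidewire_arc = NULL, i0 = 1e4) {
  if (is.null(plaques)) {
    plaques <- tibble::tibble(frame_start = integer(), frame_end = integer(),
                              arc_start_deg = numeric(),
                              arc_extent_deg = numeric(),
                              depth_start_mm = numeric(),
                              depth_end_mm = numeric(), mu = numeric())
  }
  plaques <- tibble::as_tibble(plaques)
  stopifnot(n_frames >= 1L, all(lumen_radius > 0), wall_thickness > 0,
            background_mu > 0, background_mu <= 12, i0 > 0)
  if (nrow(plaques)) {
    stopifnot(all(plaques$mu > 0), all(plaques$mu <= 12),
              all(plaques$arc_start_deg >= 0),
              all(plaques$arc_start_deg < 360),
              all(plaques$arc_extent_deg > 0),
              all(plaques$arc_extent_deg <= 360),
              all(plaques$frame_start >= 0),
              all(plaques$frame_start < plaques$frame_end))
    if (any(plaques$frame_end > n_frames)) {
      stop("plaque frame range outside the pullback", call. = FALSE)
    }
    if (any(plaques$depth_start_mm < 0 |
            plaques$depth_end_mm > wall_thickness |
            plaques$depth_start_mm >= plaques$depth_end_mm)) {
      stop("plaque depth range outside the wall", call. = FALSE)
    }
  }
  structure(
    list(n_frames = as.integer(n_frames), lumen_radius = lumen_radius,
         wall_thickness = wall_thickness, background_mu = background_mu,
         plaques = plaques, guidewire_arc = guidewire_arc, i0 = i0),
    class = "tissue_scene"
  )
}

#' Noise model for the simulator
#'
#' Speckle is modelled as independent unit-mean exponential multiplicative
#' noise on the signal (the intensity statistics of fully developed
#' speckle); the additive floor represents detection noise and is added to
#' every sample.
#'
#' @param speckle `"exponential-multiplicative"` or `"none"`.
#' @param additive_floor Additive noise-floor intensity level (>= 0).
#' @param seed Integer RNG seed; identical seeds give bit-identical output.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(speckle = c("exponential-multiplicative", "none"),
                        additive_floor = 1, seed = 1L) {
  speckle <- match.arg(speckle)
  stopifnot(additive_floor >= 0, length(seed) == 1L)
  structure(list(speckle = speckle, additive_floor = as.numeric(additive_floor),
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Forward-simulate a polar OCT pullback
#'
#' Generates the detected intensity per Eq.-style single scattering:
#' `I(r) = T(r) S(r) I0 exp(-integral of mu from the lumen to r)`, with the
#' attenuation path accumulated at single pass so that slope fitting of the
#' model recovers the generator's `mu_t` directly (the round-trip factor is
#' absorbed into `mu_t` by convention). Above the lumen the intensity is
#' the additive floor only; speckle multiplies the tissue signal per sample.
#' Contours are exact from the scene; the returned truth volume carries the
#' per-sample `mu_t` actually used.
#'
#' @param scene A [tissue_scene()].
#' @param geometry An [oct_geometry()].
#' @param system A [system_model()]; default no compensation structure.
#' @param noise A [noise_model()].
#' @return List with elements `pullback` ([oct_pullback()]), `contours`
#'   ([wall_contours()]), and `truth` ([attenuation_volume()]).
#' @export
generate_pullback <- function(scene, geometry,
                              system = identity_system(),
                              noise = noise_model()) {
  stopifnot(inherits(scene, "tissue_scene"),
            inherits(geometry, "oct_geometry"),
            inherits(noise, "noise_model"))
  nf <- scene$n_frames
  na <- geometry$n_alines
  pitch <- geometry$axial_pitch
  lumen_r <- scene$lumen_radius
  if (!is.matrix(lumen_r)) lumen_r <- matrix(lumen_r, nf, na)
  stopifnot(identical(dim(lumen_r), c(nf, na)))
  lumen_idx <- round((lumen_r - geometry$catheter_offset) / pitch)
  if (any(lumen_idx < 0)) {
    stop("lumen radius falls before the first axial sample", call. = FALSE)
  }
  wall_samples <- ceiling(scene$wall_thickness / pitch)
  ns <- as.integer(max(lumen_idx) + wall_samples +
                     ceiling(0.1 / pitch) + 1L)
  iel_idx <- lumen_idx + wall_samples

  r <- radial_distance(geometry, 0:(ns - 1L))
  comp <- compensation_curve(system, r)
  angles <- aline_angle(geometry, 0:(na - 1L))

  mu <- array(NA_real_, dim = c(nf, na, ns))
  intensity <- array(noise$additive_floor, dim = c(nf, na, ns))

  in_arc <- function(theta, start, extent) {
    ((theta - start) %% 360) < extent
  }

  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  })
  set.seed(noise$seed)

  for (f in seq_len(nf)) {
    pl <- scene$plaques[scene$plaques$frame_start <= f - 1L &
                          scene$plaques$frame_end > f - 1L, , drop = FALSE]
    for (a in seq_len(na)) {
      s0 <- lumen_idx[f, a]
      depth <- (seq(s0, ns - 1L) - s0) * pitch  # mm below the lumen border
      mu_line <- rep(scene$background_mu, length(depth))
      if (nrow(pl)) {
        for (p in seq_len(nrow(pl))) {
          if (in_arc(angles[a], pl$arc_start_deg[p], pl$arc_extent_deg[p])) {
            sel <- depth >= pl$depth_start_mm[p] & depth < pl$depth_end_mm[p]
            mu_line[sel] <- pl$mu[p]
          }
        }
      }
      mu[f, a, (s0 + 1L):ns] <- mu_line
      # cumulative single-pass attenuation from the lumen border
      path <- cumsum(c(0, mu_line[-length(mu_line)])) * pitch
      signal <- comp[(s0 + 1L):ns] * scene$i0 * exp(-path)
      if (noise$speckle == "exponential-multiplicative") {
        signal <- signal * stats::rexp(length(signal))
      }
      intensity[f, a, (s0 + 1L):ns] <- signal + noise$additive_floor
    }
  }

  valid <- matrix(TRUE, nf, na)
  if (!is.null(scene$guidewire_arc)) {
    shadow <- in_arc(angles, scene$guidewire_arc[1], scene$guidewire_arc[2])
    valid[, shadow] <- FALSE
    intensity[, shadow, ] <- noise$additive_floor
  }
  pullback <- oct_pullback(intensity, geometry,
                           noise_floor = noise$additive_floor)
  contours <- wall_contours(lumen = matrix(as.numeric(lumen_idx), nf, na),
                            iel = matrix(as.numeric(iel_idx), nf, na),
                            valid = valid, n_samples = ns)
  truth <- attenuation_volume(mu, geometry = geometry)
  list(pullback = pullback, contours = contours, truth = truth)
}

#' Simulate a cohort of plaque segments with ground-truth lipid records
#'
#' Draws `n_segments` single-plaque segments whose lipid arc and length
#' follow truncated normal distributions centred on typical ex-vivo manual
#' reads (arc 81.98 +/- 45 degrees, length 3.9 +/- 2.1 mm), with a fixed
#' fraction of lipid-free segments (default 8 of 23). Each segment is an
#' independent short pullback containing one lipid plaque of elevated
#' attenuation; the manual-style lipid record (per-frame arcs) is derived
#' from the scene geometry, never from the images.
#'
#' @param n_segments Number of segments (>= 3).
#' @param arc_distribution `c(median_deg, spread_deg)` of the plaque arc.
#' @param length_distribution `c(median_mm, spread_mm)` of the lipid length.
#' @param mu_lipid,mu_background Plaque and background attenuation, 1/mm.
#' @param p_no_lipid Fraction of segments with no lipid
#'   (`round(p * n_segments)` segments are drawn lipid-free).
#' @param n_frames Frames per segment.
#' @param geometry Acquisition geometry for every segment.
#' @param system System model used in generation (and to be used,
#'   matched, in fitting).
#' @param speckle,additive_floor Noise settings (see [noise_model()]).
#' @param seed Integer master seed; per-segment seeds derive from it.
#' @return List of length `n_segments`; each element has `pullback`,
#'   `contours`, `truth`, `record` (tibble `segment_id, frame, arc_deg`),
#'   `segment` (one-row segment table), and `scene`.
#' @export
generate_cohort <- function(n_segments = 23L,
                            arc_distribution = c(81.98, 45),
                            length_distribution = c(3.9, 2.1),
                            mu_lipid = 10, mu_background = 4,
                            p_no_lipid = 8 / 23,
                            n_frames = 25L,
                            geometry = oct_geometry(axial_pitch = 0.005,
                                                    n_alines = 36L,
                                                    frame_pitch = 0.2,
                                                    catheter_offset = 0.9),
                            system = identity_system(),
                            speckle = "exponential-multiplicative",
                            additive_floor = 1,
                            seed = 1L) {
  stopifnot(n_segments >= 3L, length(arc_distribution) == 2L,
            length(length_distribution) == 2L,
            all(arc_distribution > 0), all(length_distribution > 0),
            mu_lipid > 0, mu_lipid <= 12, mu_background > 0,
            p_no_lipid >= 0, p_no_lipid <= 1)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  })
  set.seed(seed)

  n_zero <- round(p_no_lipid * n_segments)
  lipid_free <- seq_len(n_segments) %in% sample(n_segments, n_zero)
  span_mm <- n_frames * geometry$frame_pitch
  arcs <- pmin(pmax(stats::rnorm(n_segments, arc_distribution[1],
                                 arc_distribution[2]), 15), 340)
  lens <- pmin(pmax(stats::rnorm(n_segments, length_distribution[1],
                                 length_distribution[2]),
                    geometry$frame_pitch), span_mm - 2 * geometry$frame_pitch)
  arc_starts <- stats::runif(n_segments, 0, 360)
  seg_seeds <- sample.int(2^30, n_segments)

  lapply(seq_len(n_segments), function(i) {
    sid <- sprintf("seg_%02d", i)
    if (lipid_free[i]) {
      plaques <- NULL
      rec_arcs <- rep(0, n_frames)
    } else {
      n_lip <- max(1L, round(lens[i] / geometry$frame_pitch))
      f0 <- sample.int(n_frames - n_lip + 1L, 1L) - 1L
      plaques <- tibble::tibble(
        frame_start = f0, frame_end = f0 + n_lip,
        arc_start_deg = arc_starts[i], arc_extent_deg = arcs[i],
        depth_start_mm = 0.05, depth_end_mm = 0.55, mu = mu_lipid)
      rec_arcs <- rep(0, n_frames)
      rec_arcs[(f0 + 1L):(f0 + n_lip)] <- arcs[i]
    }
    scene <- tissue_scene(n_frames = n_frames, lumen_radius = 1.0,
                          wall_thickness = 0.8,
                          background_mu = mu_background, plaques = plaques)
    sim <- generate_pullback(
      scene, geometry, system,
      noise_model(speckle = speckle, additive_floor = additive_floor,
                  seed = seg_seeds[i]))
    list(
      pullback = sim$pullback, contours = sim$contours, truth = sim$truth,
      record = tibble::tibble(segment_id = sid, frame = 0:(n_frames - 1L),
                              arc_deg = rec_arcs),
      segment = tibble::tibble(segment_id = sid, frame_start = 0L,
                               frame_end = n_frames),
      scene = scene
    )
  })
}

#' Run the full analysis chain on a simulated cohort
#'
#' For every segment: fit the attenuation volume, build the en-face map,
#' and evaluate the IPA family; then score the ground-truth lipid records
#' and sweep the threshold grid against the scores.
#'
#' @param cohort Output of [generate_cohort()].
#' @param system A [system_model()] (should match the one used to
#'   generate).
#' @param config A [fit_config()].
#' @param grid Threshold grid, 1/mm.
#' @param depth_fallback En-face fallback depth, mm.
#' @return An `ipa_sweep` object (see [sweep_thresholds()]).
#' @export
cohort_sweep <- function(cohort, system = identity_system(),
                         config = fit_config(), grid = threshold_grid(),
                         depth_fallback = 1) {
  ipa_results <- purrr::map_dfr(cohort, function(seg) {
    vol <- fit_pullback(seg$pullback, seg$contours, system, config)
    map <- build_enface(vol, seg$contours, depth_fallback)
    fam <- ipa_family(map, seg$segment, grid)
    fam
  })
  records <- purrr::map_dfr(cohort, "record")
  scores <- lipid_score(records,
                        frame_pitch = cohort[[1]]$pullback$geometry$frame_pitch)
  sweep_thresholds(scores, ipa_results)
}
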