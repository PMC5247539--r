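small_geom <- function(na_ = 12L) {
  oct_geometry(axial_pitch = 0.01, n_alines = na_, frame_pitch = 0.2,
               catheter_offset = 0.9)
}

test_that("the generator is bit-reproducible under a fixed seed", {
  scene <- tissue_scene(n_frames = 3, background_mu = 4,
                        plaques = tibble::tibble(
                          frame_start = 0L, frame_end = 2L,
                          arc_start_deg = 30, arc_extent_deg = 90,
                          depth_start_mm = 0.1, depth_end_mm = 0.4, mu = 10))
  a <- generate_pullback(scene, small_geom(), noise = noise_model(seed = 7))
  b <- generate_pullback(scene, small_geom(), noise = noise_model(seed = 7))
  expect_identical(a$pullback$intensity, b$pullback$intensity)
  expect_identical(a$truth$mu, b$truth$mu)
  c <- generate_pullback(scene, small_geom(), noise = noise_model(seed = 8))
  expect_false(identical(a$pullback$intensity, c$pullback$intensity))
})

test_that("noiseless uniform scenes are recovered end-to-end", {
  scene <- tissue_scene(n_frames = 2, background_mu = 3)
  sim <- generate_pullback(scene, small_geom(6L),
                           noise = noise_model(speckle = "none",
                                               additive_floor = 0))
  vol <- fit_pullback(sim$pullback, sim$contours)
  est <- vol$mu[is.finite(vol$mu)]
  expect_gt(length(est), 100)
  expect_true(all(abs(est - 3) < 1e-6))
})

test_that("intensity above the lumen is the floor and decays inside tissue", {
  scene <- tissue_scene(n_frames = 1, background_mu = 5)
  sim <- generate_pullback(scene, small_geom(6L),
                           noise = noise_model(speckle = "none",
                                               additive_floor = 2))
  lum <- sim$contours$lumen[1, 1]
  line <- sim$pullback$intensity[1, 1, ]
  expect_true(all(line[seq_len(lum)] == 2))
  tissue <- line[(lum + 1):length(line)]
  expect_true(all(diff(tissue) < 0))  # monotone decay, noiseless
  expect_equal(sim$pullback$noise_floor, 2)
})

test_that("speckle is unit-mean exponential to within 1 percent", {
  scene <- tissue_scene(n_frames = 30, background_mu = 2, i0 = 1)
  geom <- small_geom(40L)
  sim <- generate_pullback(scene, geom, noise = noise_model(
    speckle = "exponential-multiplicative", additive_floor = 0, seed = 5))
  ref <- generate_pullback(scene, geom, noise = noise_model(
    speckle = "none", additive_floor = 0))
  sel <- ref$pullback$intensity > 0
  factors <- sim$pullback$intensity[sel] / ref$pullback$intensity[sel]
  expect_gt(length(factors), 1e5)
  expect_lt(abs(mean(factors) - 1), 0.01)
  # exponential shape: variance of a unit-mean exponential is 1
  expect_lt(abs(stats::var(factors) - 1), 0.05)
})

test_that("the truth volume's en-face maximum equals the plaque mu exactly", {
  plaque <- tibble::tibble(frame_start = 2L, frame_end = 8L,
                           arc_start_deg = 100, arc_extent_deg = 120,
                           depth_start_mm = 0.1, depth_end_mm = 0.4,
                           mu = 9.5)
  scene <- tissue_scene(n_frames = 10, background_mu = 4, plaques = plaque)
  geom <- small_geom(24L)
  sim <- generate_pullback(scene, geom, noise = noise_model(speckle = "none"))
  m <- build_enface(sim$truth, sim$contours)
  angles <- aline_angle(geom, 0:23)
  in_arc <- ((angles - 100) %% 360) < 120
  expect_true(all(m$values[3:8, in_arc] == 9.5))
  expect_true(all(m$values[, !in_arc] == 4))
  expect_true(all(m$values[c(1, 2, 9, 10), ] == 4))
})

test_that("plaques outside the wall or pullback are rejected", {
  bad_depth <- tibble::tibble(frame_start = 0L, frame_end = 2L,
                              arc_start_deg = 0, arc_extent_deg = 90,
                              depth_start_mm = 0.5, depth_end_mm = 1.2,
                              mu = 10)
  expect_error(tissue_scene(n_frames = 3, wall_thickness = 0.8,
                            plaques = bad_depth), "wall")
  bad_frames <- dplyr::mutate(bad_depth, depth_end_mm = 0.7, frame_end = 9L)
  expect_error(tissue_scene(n_frames = 3, plaques = bad_frames), "pullback")
})

test_that("guide-wire shadows are masked invalid and carry no signal", {
  scene <- tissue_scene(n_frames = 2, background_mu = 4,
                        guidewire_arc = c(350, 30))
  geom <- small_geom(36L)
  sim <- generate_pullback(scene, geom, noise = noise_model(
    speckle = "none", additive_floor = 1))
  angles <- aline_angle(geom, 0:35)
  shadow <- ((angles - 350) %% 360) < 30
  expect_true(any(shadow) && any(!shadow))
  expect_true(all(!sim$contours$valid[, shadow]))
  expect_true(all(sim$contours$valid[, !shadow]))
  expect_true(all(sim$pullback$intensity[, shadow, ] == 1))
})

test_that("cohorts honour the lipid-free fraction and score bookkeeping", {
  coh <- generate_cohort(n_segments = 23, seed = 9, n_frames = 10,
                         geometry = oct_geometry(axial_pitch = 0.01,
                                                 n_alines = 12L,
                                                 frame_pitch = 0.2,
                                                 catheter_offset = 0.9))
  expect_length(coh, 23L)
  records <- purrr::map_dfr(coh, "record")
  scores <- lipid_score(records, frame_pitch = 0.2)
  expect_equal(sum(scores$score == 0), 8L)  # 8 of 23 lipid-free
  # scores follow directly from the scene geometry
  for (i in c(1, 5, 23)) {
    pl <- coh[[i]]$scene$plaques
    sid <- coh[[i]]$segment$segment_id
    want <- if (nrow(pl) == 0) 0 else {
      pl$arc_extent_deg * (pl$frame_end - pl$frame_start) * 0.2
    }
    expect_equal(scores$score[scores$segment_id == sid], want)
  }
  # all-lipid-free cohorts score zero everywhere
  coh0 <- generate_cohort(n_segments = 4, p_no_lipid = 1, seed = 2,
                          n_frames = 6)
  rec0 <- purrr::map_dfr(coh0, "record")
  expect_true(all(lipid_score(rec0, 0.2)$score == 0))
  # reproducibility
  coh_b <- generate_cohort(n_segments = 4, p_no_lipid = 1, seed = 2,
                           n_frames = 6)
  expect_identical(purrr::map(coh_b, "pullback"),
                   purrr::map(coh0, "pullback"))
})
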