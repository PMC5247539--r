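test_that("compensation curve matches the closed forms", {
  sys0 <- system_model(focus_position = 1, apparent_rayleigh_length = 0.5,
                       rolloff_length = NA)
  expect_equal(compensation_curve(sys0, 1), 1.0)
  # Lorentzian half-width: one Rayleigh length off focus halves the gate
  expect_equal(compensation_curve(sys0, 1.5), 0.5)
  sys <- system_model(focus_position = 1, apparent_rayleigh_length = 0.5,
                      rolloff_length = 4)
  expect_equal(compensation_curve(sys, 2), (1 / 5) * exp(-0.25),
               tolerance = 1e-12)
  expect_equal((1 / 5) * exp(-0.25), 0.15576, tolerance = 1e-4)
  expect_equal(compensation_curve(identity_system(), c(0, 1, 7)),
               c(1, 1, 1))
})

test_that("log-linear window fit is exact on noiseless decays", {
  r <- seq(0.5, 1.1, by = 0.01)
  fit <- fit_window(3.7 * exp(-2.5 * r), r)
  expect_equal(fit$mu, 2.5, tolerance = 1e-9)
  expect_equal(fit$i0, 3.7, tolerance = 1e-9)
  expect_equal(fit$quality, 1.0)

  # constant segment: zero slope, zero residual -> quality 1 by convention
  fit_const <- fit_window(rep(4.2, 30), seq(0.5, 0.79, by = 0.01))
  expect_equal(fit_const$mu, 0.0)
  expect_equal(fit_const$quality, 1.0)

  # matched compensation cancels exactly
  sys <- system_model(focus_position = 1, apparent_rayleigh_length = 0.5,
                      rolloff_length = 4)
  intensity <- decay_intensity(6, r, i0 = 2, system = sys)
  fit_sys <- fit_window(intensity, r, sys)
  expect_equal(fit_sys$mu, 6, tolerance = 1e-9)
})

test_that("unmatched compensation biases the slope by the optics log-slope", {
  sys <- system_model(focus_position = 1.3, apparent_rayleigh_length = 0.4,
                      rolloff_length = 3)
  r <- seq(0.8, 1.2, by = 0.005)
  mu_true <- 5
  intensity <- decay_intensity(mu_true, r, i0 = 1, system = sys)
  fit_id <- fit_window(intensity, r, identity_system())
  # log I = log(TS) + log i0 - mu r, and OLS is linear in the response:
  # the bias equals the OLS slope of log(TS) on r
  lts <- log(compensation_curve(sys, r))
  bias <- sum((r - mean(r)) * (lts - mean(lts))) / sum((r - mean(r))^2)
  expect_equal(fit_id$mu, mu_true - bias, tolerance = 1e-9)
  expect_false(abs(bias) < 0.1)  # the bias is material at this geometry
})

test_that("insufficient or non-positive samples signal no fit", {
  r <- seq(0.5, 0.54, by = 0.01)
  out <- fit_window(c(1, 0, 0, 0, 0), r)
  expect_true(is.na(out$mu))
  expect_lt(out$n_used, 3)
  expect_error(fit_window(c(1, 2, 3), c(0.5, 0.5, 0.6)))  # r not increasing
})

test_that("noiseless homogeneous A-lines are recovered exactly for any windows", {
  for (wl in list(c(0.6, 0.4, 0.2), 0.3, c(0.5, 0.1))) {
    sim <- flat_pullback(mu = 3, ns = 120L)
    cfg <- fit_config(window_lengths = wl)
    res <- fit_aline(sim$pullback, 0L, 0L, sim$contours, config = cfg)
    est <- res$mu[is.finite(res$mu)]
    expect_gt(length(est), 50)
    expect_true(all(abs(est - 3) < 1e-6))
  }
})

test_that("exactness holds across the clamp range in the noiseless limit", {
  for (mu in c(0, 0.5, 2, 5, 8, 11, 12)) {
    sim <- flat_pullback(mu = mu, ns = 100L)
    res <- fit_aline(sim$pullback, 0L, 0L, sim$contours)
    est <- res$mu[is.finite(res$mu)]
    expect_true(all(abs(est - mu) < 1e-6),
                label = paste("recovery at mu =", mu))
  }
})

test_that("two-layer walls are recovered away from the interface", {
  geom <- oct_geometry(axial_pitch = 0.005, n_alines = 4, frame_pitch = 0.2,
                       catheter_offset = 0.5)
  ns <- 220L
  lumen_idx <- 10L
  r <- radial_distance(geom, 0:(ns - 1))
  r_lum <- r[lumen_idx + 1]
  depth <- pmax(r - r_lum, 0)
  half <- 0.5  # each layer 0.5 mm thick
  mu_profile <- ifelse(depth < half, 2, 10)
  path <- cumsum(c(0, mu_profile[-ns]) * 0.005)
  line <- exp(-path)
  line[seq_len(lumen_idx)] <- 0
  intensity <- aperm(array(line, dim = c(ns, 4, 1)), c(3, 2, 1))
  pb <- oct_pullback(intensity, geom, noise_floor = 0)
  ct <- wall_contours(matrix(lumen_idx, 1, 4), matrix(ns - 10, 1, 4),
                      matrix(TRUE, 1, 4), n_samples = ns)
  cfg <- fit_config(window_lengths = c(0.25, 0.15), min_quality = 0.9)
  res <- fit_aline(pb, 0L, 0L, ct, config = cfg)
  # probe well inside each layer (>= one window length from the interface)
  in1 <- which(depth > 0.05 & depth < 0.2)
  in2 <- which(depth > 0.8 & depth < 0.95)
  expect_true(all(abs(res$mu[in1] - 2) < 0.1))
  expect_true(all(abs(res$mu[in2] - 10) < 0.1))
})

test_that("estimates are clamped to the configured range at storage", {
  # rising noiseless signal => negative fitted attenuation, clamped to 0
  geom <- oct_geometry(axial_pitch = 0.01, n_alines = 4, frame_pitch = 0.2,
                       catheter_offset = 0.5)
  ns <- 60L
  r <- radial_distance(geom, 0:(ns - 1))
  line <- exp(+0.5 * r)
  intensity <- aperm(array(line, dim = c(ns, 4, 1)), c(3, 2, 1))
  pb <- oct_pullback(intensity, geom, noise_floor = 0)
  ct <- wall_contours(matrix(0, 1, 4), matrix(ns - 5, 1, 4),
                      matrix(TRUE, 1, 4), n_samples = ns)
  res <- fit_aline(pb, 0L, 0L, ct)
  expect_true(all(res$mu[is.finite(res$mu)] == 0))
  # whereas the raw window fit is negative
  expect_lt(fit_window(line, r)$mu, 0)
})

test_that("fit_pullback composes fit_aline and honours the validity mask", {
  sim <- flat_pullback(mu = 4, nf = 2L, na_ = 4L, ns = 100L)
  ct_all_invalid <- wall_contours(sim$contours$lumen, sim$contours$iel,
                                  matrix(FALSE, 2, 4))
  vol0 <- fit_pullback(sim$pullback, ct_all_invalid)
  expect_true(all(!is.finite(vol0$mu)))

  one_valid <- matrix(FALSE, 2, 4); one_valid[2, 3] <- TRUE
  ct1 <- wall_contours(sim$contours$lumen, sim$contours$iel, one_valid)
  vol1 <- fit_pullback(sim$pullback, ct1)
  ref <- fit_aline(sim$pullback, 1L, 2L, sim$contours)
  expect_equal(vol1$mu[2, 3, ], ref$mu)
  expect_true(all(!is.finite(vol1$mu[1, , ])))

  # determinism: identical inputs, identical output
  vol2 <- fit_pullback(sim$pullback, ct1)
  expect_identical(vol1$mu, vol2$mu)
})

test_that("attenuation volume TIFF round-trip preserves estimates and NA", {
  sim <- flat_pullback(mu = 6, nf = 2L, na_ = 4L, ns = 80L)
  vol <- fit_pullback(sim$pullback, sim$contours)
  path <- file.path(withr::local_tempdir(), "mu.tif")
  write_attenuation(vol, path)
  back <- read_attenuation(path)
  expect_equal(back$mu, vol$mu, tolerance = 1e-6)
  expect_identical(is.na(back$mu), is.na(vol$mu))
  expect_equal(back$geometry, vol$geometry)
})
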