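test_that("lipid score is mean arc over lipid frames times lipid length", {
  zero <- tibble::tibble(segment_id = "z", frame = 0:9, arc_deg = 0)
  s0 <- lipid_score(zero, frame_pitch = 0.2)
  expect_equal(s0$score, 0)
  expect_equal(s0$mean_arc, 0)
  expect_equal(s0$lipid_length, 0)

  one <- tibble::tibble(segment_id = "o", frame = 0:4,
                        arc_deg = c(0, 90, 0, 0, 0))
  s1 <- lipid_score(one, frame_pitch = 0.2)
  expect_equal(s1$lipid_length, 0.2)
  expect_equal(s1$mean_arc, 90)
  expect_equal(s1$score, 18)

  # a typical ex-vivo segment: arc 81.98 deg over 3.9 mm
  arcs <- tibble::tibble(segment_id = "t", frame = 0:24,
                         arc_deg = c(rep(81.98, 20), rep(0, 5)))
  st <- lipid_score(arcs, frame_pitch = 0.195)
  expect_equal(st$lipid_length, 3.9)
  expect_equal(st$score, 81.98 * 3.9)
  expect_equal(st$score, 319.722, tolerance = 1e-6)

  # zero-arc frames dilute the mean only under mean_over = "all_frames"
  mixed <- tibble::tibble(segment_id = "m", frame = 0:3,
                          arc_deg = c(100, 50, 0, 0))
  expect_equal(lipid_score(mixed, 0.2)$mean_arc, 75)
  expect_equal(lipid_score(mixed, 0.2, mean_over = "all_frames")$mean_arc,
               37.5)
  expect_error(lipid_score(dplyr::mutate(mixed, arc_deg = arc_deg * 10),
                           0.2), "360")
})

test_that("pearson matches the product-moment formula and its invariances", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson(x, 2 * x + 1), 1.0)
  expect_equal(pearson(x, -x), -1.0)
  expect_equal(pearson(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson(x, rep(2, 5)), "zero variance")

  set.seed(41)
  for (rep in 1:10) {
    a <- rnorm(15); b <- rnorm(15)
    r0 <- pearson(a, b)
    expect_equal(pearson(3 * a - 7, b), r0)
    expect_equal(pearson(a, 0.1 * b + 100), r0)
    expect_equal(pearson(-2 * a, b), -r0)
  }
})

test_that("the sweep finds the threshold where IPA tracks the score", {
  scores <- tibble::tibble(segment_id = paste0("s", 1:6),
                           score = c(0, 50, 120, 200, 340, 610))
  grid <- threshold_grid()
  set.seed(42)
  fams <- purrr::map_dfr(seq_len(6), function(i) {
    ipa <- runif(length(grid), 0, 1000)       # noise at other thresholds
    ipa[grid == 5] <- scores$score[i]          # perfect correlate at x = 5
    tibble::tibble(segment_id = paste0("s", i), threshold = grid, ipa = ipa)
  })
  sw <- sweep_thresholds(scores, fams)
  expect_equal(sw$best_threshold, 5)
  expect_equal(sw$best_r, 1.0)
  expect_equal(sw$slope, 1, tolerance = 1e-12)
  expect_equal(sw$intercept, 0, tolerance = 1e-9)
  expect_lt(sw$p_value, 1e-6)

  gl <- glance(sw)
  expect_equal(gl$best_threshold, 5)
  expect_equal(gl$r2, 1)
  td <- tidy(sw)
  expect_equal(nrow(td), length(grid))
  expect_s3_class(autoplot(sw), "ggplot")
})

test_that("zero-variance thresholds are skipped, not fatal", {
  scores <- tibble::tibble(segment_id = c("a", "b", "c", "d"),
                           score = c(0, 100, 200, 300))
  grid <- c(2, 4, 6, 8)
  fams <- purrr::map_dfr(c("a", "b", "c", "d"), function(id) {
    s <- scores$score[scores$segment_id == id]
    tibble::tibble(segment_id = id, threshold = grid,
                   ipa = c(500,           # constant at x = 2 -> skipped
                           s * 2, s, s / 2))
  })
  sw <- sweep_thresholds(scores, fams)
  td <- tidy(sw)
  expect_true(td$skipped[td$threshold == 2])
  expect_true(is.na(td$r[td$threshold == 2]))
  expect_false(any(td$skipped[td$threshold > 2]))
  # x = 4, 6, 8 all have r = 1: the tie goes to the lowest threshold
  expect_equal(sw$best_threshold, 4)
  expect_equal(sw$best_r, 1)
  # with fewer than 3 usable thresholds the sweep fails loudly
  expect_error(sweep_thresholds(scores,
                                dplyr::filter(fams, threshold %in% c(2, 4, 6),
                                              threshold != 4)),
               "fewer than 3 thresholds")
})

test_that("sweep argmax agrees with a brute-force loop on random data", {
  set.seed(43)
  grid <- threshold_grid()
  for (rep in 1:5) {
    n_seg <- 8
    scores <- tibble::tibble(segment_id = paste0("s", 1:n_seg),
                             score = runif(n_seg, 0, 600))
    fams <- purrr::map_dfr(seq_len(n_seg), function(i) {
      tibble::tibble(segment_id = paste0("s", i), threshold = grid,
                     ipa = runif(length(grid), 0, 1000))
    })
    sw <- sweep_thresholds(scores, fams)
    brute <- vapply(grid, function(x) {
      sub <- fams[fams$threshold == x, ]
      sub <- sub[match(scores$segment_id, sub$segment_id), ]
      stats::cor(sub$ipa, scores$score)
    }, numeric(1))
    expect_equal(sw$best_threshold, grid[which.max(brute)])
    expect_equal(sw$best_r, max(brute))
  }
})

test_that("sweeps need at least 3 segments and matching segment sets", {
  scores <- tibble::tibble(segment_id = c("a", "b"), score = c(1, 2))
  fams <- tibble::tibble(segment_id = c("a", "b"), threshold = 1,
                         ipa = c(1, 2))
  expect_error(sweep_thresholds(scores, fams), "3 segments")
  scores3 <- tibble::tibble(segment_id = c("a", "b", "c"),
                            score = c(1, 2, 3))
  expect_error(sweep_thresholds(scores3, fams), "different segment sets")
})
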