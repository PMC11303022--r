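roi_fixations <- function(geom, n_per_side = 10, shift = 0, jitter = 0,
                          seed = 1) {
  set.seed(seed)
  lc <- gazebias:::rect_center(geom$left_roi)
  rc <- gazebias:::rect_center(geom$right_roi)
  x <- c(rep(lc[["x"]], n_per_side), rep(rc[["x"]], n_per_side)) + shift +
    rnorm(2 * n_per_side, 0, jitter)
  data.frame(trial_id = "T1", start_ms = seq(0, by = 100,
                                             length.out = 2 * n_per_side),
             end_ms = 80 + seq(0, by = 100, length.out = 2 * n_per_side),
             duration_ms = 80, centroid_x_px = x,
             centroid_y_px = lc[["y"]], n_samples = 5,
             stringsAsFactors = FALSE)
}

test_that("a known shift is recovered with opposite sign and applied", {
  geom <- screen_geometry()
  fx <- roi_fixations(geom, shift = -141, jitter = 6)
  est <- estimate_session_offset(fx, geom)
  expect_true(est$applied)
  expect_lt(abs(est$offset_px - 141), 5)
})

test_that("well-calibrated sessions are left untouched", {
  geom <- screen_geometry()
  est <- estimate_session_offset(roi_fixations(geom, jitter = 4), geom)
  expect_false(est$applied)
  expect_lt(abs(est$offset_px), 10)
})

test_that("degenerate sessions (one cluster or too few fixations) are flagged, not corrected", {
  geom <- screen_geometry()
  one_side <- roi_fixations(geom, n_per_side = 8)
  one_side$centroid_x_px <- gazebias:::rect_center(geom$left_roi)[["x"]] +
    rnorm(16, 0, 3)
  est <- estimate_session_offset(one_side, geom)
  expect_false(est$applied)
  expect_true(est$degenerate)
  expect_warning(est2 <- estimate_session_offset(one_side[1:2, ], geom),
                 "fixations")
  expect_false(est2$applied)
})

test_that("applying an offset is pure and invertible", {
  ds <- quick_dataset(9)
  g2 <- apply_offset(apply_offset(ds$gaze, 134), -134)
  expect_equal(g2$x_px, ds$gaze$x_px)
  expect_identical(apply_offset(ds$gaze, 0), ds$gaze)
})

test_that("a corrected session re-estimates below the application threshold", {
  for (seed in c(2, 5, 11)) {
    ds <- simulate_gaze(gen_config(n_subjects = 1, sessions_per_subject = 1,
                                   trials_per_session = 12,
                                   missing_trial_prob = 0,
                                   drift_px_by_session = c("1" = -120),
                                   seed = seed))
    fx <- detect_fixations(ds$gaze)
    est <- estimate_session_offset(fx, ds$geometry)
    expect_true(est$applied)
    redo <- estimate_session_offset(apply_offset(fx, est$offset_px),
                                    ds$geometry)
    expect_lt(abs(redo$offset_px), 50)
    expect_false(redo$applied)
  }
})

test_that("correct_drift corrects only the drifted sessions of a multi-session set", {
  ds <- simulate_gaze(gen_config(n_subjects = 2, sessions_per_subject = 3,
                                 trials_per_session = 10,
                                 missing_trial_prob = 0,
                                 drift_px_by_session = c("2" = 134),
                                 seed = 13))
  fx <- detect_fixations(ds$gaze)
  dr <- correct_drift(fx, ds$manifest, ds$geometry)
  expect_equal(dr$report$applied, rep(c(FALSE, TRUE, FALSE), 2))
  corrected <- dr$report$offset_px[dr$report$applied]
  expect_true(all(abs(corrected + 134) < 15))
})
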