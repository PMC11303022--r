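test_that("generation is deterministic under a fixed seed and leaves the session RNG alone", {
  cfg <- gen_config(n_subjects = 1, sessions_per_subject = 2,
                    trials_per_session = 6, seed = 33)
  set.seed(999); before <- rnorm(1)
  a <- simulate_gaze(cfg)
  set.seed(999)
  b <- simulate_gaze(cfg)
  expect_identical(a, b)
  set.seed(999); expect_identical(rnorm(1), before)
})

test_that("an unbiased generator yields mean dwell proportion 0.5", {
  cfg <- gen_config(n_subjects = 5, sessions_per_subject = 10,
                    trials_per_session = 100,
                    bias_by_condition = setNames(rep(0.5, 10),
                                                 names(gazebias:::default_bias())),
                    zoi_prob = 0, missing_trial_prob = 0, overrun_prob = 0,
                    subject_sd = 0, session_sd = 0, seed = 7)
  ds <- simulate_gaze(cfg, emit_gaze = FALSE)
  expect_gte(nrow(ds$truth), 5000)
  expect_lt(abs(mean(ds$truth$y_realized) - 0.5), 0.02)
})

test_that("boundary-inflation and condition-mean rates converge to the configured values", {
  bias <- setNames(rep(c(0.60, 0.45), 5), names(gazebias:::default_bias()))
  cfg <- gen_config(n_subjects = 5, sessions_per_subject = 10,
                    trials_per_session = 120, bias_by_condition = bias,
                    zoi_prob = 0.15, coi_prob = 0.7,
                    subject_sd = 0, session_sd = 0,
                    missing_trial_prob = 0, overrun_prob = 0, seed = 12)
  ds <- simulate_gaze(cfg, emit_gaze = FALSE)
  tr <- ds$truth
  n <- nrow(tr)
  expect_gte(n, 5000)
  # inflation fraction within binomial tolerance of zoi_prob
  frac <- mean(tr$y_latent %in% c(0, 1))
  expect_lt(abs(frac - 0.15), 3 * sqrt(0.15 * 0.85 / n))
  # per-condition mean of non-inflated latent proportions within 3 MC SEs
  for (sp in species_levels()) {
    sel <- tr$species_on_scene == sp & !tr$inflated
    mc_se <- sd(tr$y_latent[sel]) / sqrt(sum(sel))
    target <- unname(bias[paste0(sp, ".distress")])
    expect_lt(abs(mean(tr$y_latent[sel]) - target), 3 * mc_se)
  }
})

test_that("the ground-truth record recomputes every dwell proportion exactly", {
  ds <- quick_dataset(5)
  tr <- ds$truth
  expect_equal(tr$y_realized,
               tr$tfd_emotional_ms / (tr$tfd_emotional_ms + tr$tfd_neutral_ms))
  # and the scored pipeline recovers it exactly on clean trials
  fx <- detect_fixations(ds$gaze)
  mt <- compute_metrics(fx, ds$geometry, trial_ids = ds$manifest$trial_id)
  sc <- filter_tfd(mt, ds$manifest)$scored
  m <- merge(sc[!sc$excluded, c("trial_id", "pld_emotion")],
             tr[, c("trial_id", "y_realized")])
  expect_equal(m$pld_emotion, m$y_realized, tolerance = 1e-12)
})

test_that("session drift shifts gaze by exactly the configured offset", {
  base <- gen_config(n_subjects = 1, sessions_per_subject = 2,
                     trials_per_session = 6, seed = 44)
  drifted <- gen_config(n_subjects = 1, sessions_per_subject = 2,
                        trials_per_session = 6, seed = 44,
                        drift_px_by_session = c("1" = 134))
  g0 <- simulate_gaze(base)$gaze
  g1 <- simulate_gaze(drifted)$gaze
  s1 <- grepl("_s01_", g0$trial_id)
  expect_equal(g1$x_px[s1], g0$x_px[s1] + 134)
  expect_equal(g1$x_px[!s1], g0$x_px[!s1])
  expect_equal(g1$y_px, g0$y_px)
})

test_that("side counterbalancing and emotion categories follow the design", {
  ds <- quick_dataset(8)
  man <- ds$manifest
  expect_true(all(man$emotion_category %in% emotion_levels()))
  sides <- tapply(man$emotional_side, paste(man$subject, man$session),
                  function(s) sum(s == "left"))
  expect_true(all(sides == 5))  # 10 trials per session, counterbalanced
})

test_that("invalid configurations are rejected", {
  expect_error(gen_config(zoi_prob = 1.4), "probabilities")
  expect_error(gen_config(precision_phi = 0), "phi")
  expect_error(gen_config(trial_duration_s = 0.2), "dwell geometry")
  expect_error(gen_config(sample_rate_hz = -1), "probabilities|sample_rate",
               ignore.case = TRUE)
})
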