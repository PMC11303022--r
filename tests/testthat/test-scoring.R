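test_that("pld_emotion follows the dwell-share formula", {
  expect_equal(pld_emotion(1.5, 1.5), 0.5)
  expect_equal(pld_emotion(2.4, 0.0), 1.0)
  expect_equal(pld_emotion(1.2, 0.8), 0.6)
  expect_true(is.na(pld_emotion(0, 0)))
  expect_error(pld_emotion(-1, 2), ">= 0")
})

test_that("pld_emotion is antisymmetric in its arguments", {
  set.seed(42)
  a <- runif(500, 0, 3); b <- runif(500, 0, 3)
  expect_equal(pld_emotion(a, b) + pld_emotion(b, a), rep(1, 500))
})

test_that("trial weights are the ratio to the subject mean and average 1", {
  expect_equal(trial_weight(2.0, 2.0), 1.0)
  expect_equal(trial_weight(1.0, 2.0), 0.5)
  expect_error(trial_weight(1.0, 0), "> 0")
  ds <- quick_dataset(21)
  fx <- detect_fixations(ds$gaze)
  mt <- compute_metrics(fx, ds$geometry, trial_ids = ds$manifest$trial_id)
  sc <- filter_tfd(mt, ds$manifest)$scored
  means <- tapply(sc$weight[!sc$excluded], sc$subject[!sc$excluded], mean)
  expect_equal(as.numeric(means), rep(1, length(means)))
  expect_true(all(sc$weight[!sc$excluded] > 0))
})

test_that("first-fixation binarization handles order, single-ROI and ties", {
  expect_equal(first_fixation_location(200, 450), 1L)
  expect_equal(first_fixation_location(450, 200), 0L)
  expect_equal(first_fixation_location(300, NA), 1L)
  expect_equal(first_fixation_location(NA, 300), 0L)
  expect_true(is.na(first_fixation_location(300, 300)))
})

test_that("scoring is invariant to mirroring the emotional side", {
  ds <- quick_dataset(31)
  fx <- detect_fixations(ds$gaze)
  mt <- compute_metrics(fx, ds$geometry, trial_ids = ds$manifest$trial_id)
  man <- ds$manifest
  # mirror: swap the ROI metrics and flip the side labels
  mt2 <- mt
  mt2[c("tfd_left_s", "tfd_right_s")] <- mt[c("tfd_right_s", "tfd_left_s")]
  mt2[c("tfd_left_unclipped_s", "tfd_right_unclipped_s")] <-
    mt[c("tfd_right_unclipped_s", "tfd_left_unclipped_s")]
  mt2[c("ttff_left_ms", "ttff_right_ms")] <- mt[c("ttff_right_ms", "ttff_left_ms")]
  man2 <- man
  man2$emotional_side <- ifelse(man$emotional_side == "left", "right", "left")
  a <- filter_tfd(mt, man)$scored
  b <- filter_tfd(mt2, man2)$scored
  expect_equal(a$pld_emotion, b$pld_emotion)
  fa <- filter_ttff(mt, man)$scored
  fb <- filter_ttff(mt2, man2)$scored
  expect_equal(fa$first_fix_emotional, fb$first_fix_emotional)
})

test_that("the exclusion ledger identity holds on randomized fixtures", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- 120
    man <- data.frame(trial_id = sprintf("T%03d", 1:n),
                      subject = sample(c("A", "B"), n, TRUE),
                      session = sample(1:3, n, TRUE),
                      species_on_scene = sample(species_levels(), n, TRUE),
                      emotion_category = sample(emotion_levels(), n, TRUE),
                      emotional_side = sample(c("left", "right"), n, TRUE),
                      stringsAsFactors = FALSE)
    tl <- round(runif(n, 0, 2), 2); tr <- round(runif(n, 0, 2), 2)
    gone <- runif(n) < 0.15
    tl[gone] <- tr[gone] <- 0
    mt <- data.frame(trial_id = man$trial_id, tfd_left_s = tl,
                     tfd_right_s = tr,
                     tfd_left_unclipped_s = tl * sample(c(1, 2), n, TRUE),
                     tfd_right_unclipped_s = tr,
                     ttff_left_ms = ifelse(runif(n) < 0.2, NA,
                                           round(runif(n, 0, 1000))),
                     ttff_right_ms = ifelse(runif(n) < 0.2, NA,
                                            round(runif(n, 0, 1000))),
                     center_ok = runif(n) < 0.7,
                     any_gaze = tl + tr > 0, stringsAsFactors = FALSE)
    for (res in list(filter_tfd(mt, man),
                     filter_ttff(mt, man, species_mode = "bonobo"),
                     filter_ttff(mt, man, species_mode = "human"))) {
      led <- res$ledger
      expect_equal(led$valid, led$total - sum(unlist(led$removed_by_reason)))
      expect_equal(sum(!res$scored$excluded), led$valid)
      expect_equal(sum(res$scored$excluded),
                   sum(unlist(led$removed_by_reason)))
    }
  }
})

test_that("a trial that is both gaze-free and overrunning counts once, under no_gaze", {
  man <- data.frame(trial_id = "T1", subject = "A", session = 1,
                    species_on_scene = "bonobo", emotion_category = "play",
                    emotional_side = "left", stringsAsFactors = FALSE)
  mt <- data.frame(trial_id = "T1", tfd_left_s = 0, tfd_right_s = 0,
                   tfd_left_unclipped_s = 4, tfd_right_unclipped_s = 0,
                   ttff_left_ms = NA_real_, ttff_right_ms = NA_real_,
                   center_ok = TRUE, any_gaze = FALSE, stringsAsFactors = FALSE)
  led <- filter_tfd(mt, man)$ledger
  expect_equal(led$removed_by_reason$no_gaze, 1)
  expect_equal(led$removed_by_reason$overrun, 0)
})

test_that("metrics/manifest mismatches abort naming the orphans", {
  ds <- quick_dataset(51)
  fx <- detect_fixations(ds$gaze)
  mt <- compute_metrics(fx, ds$geometry, trial_ids = ds$manifest$trial_id)
  expect_error(filter_tfd(mt, ds$manifest[-1, ]),
               ds$manifest$trial_id[1], fixed = TRUE)
})
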