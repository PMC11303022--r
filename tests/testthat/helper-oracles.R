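# Brute-force fixation segmentation oracle: a plain loop applying the same
# rule as the vectorized detector (valid samples, velocity below threshold,
# gap below maximum), kept deliberately naive and independent.
oracle_fixations <- function(gaze, min_duration_ms = 60,
                             velocity_threshold = 3, max_gap_ms = 75) {
  out <- list()
  runs <- list()
  cur <- integer(0)
  n <- nrow(gaze)
  flush <- function(cur) if (length(cur)) runs[[length(runs) + 1]] <<- cur
  for (i in seq_len(n)) {
    if (!gaze$valid[i]) { flush(cur); cur <- integer(0); next }
    if (length(cur) == 0) { cur <- i; next }
    j <- cur[length(cur)]
    dt <- gaze$t_ms[i] - gaze$t_ms[j]
    dist <- sqrt((gaze$x_px[i] - gaze$x_px[j])^2 +
                 (gaze$y_px[i] - gaze$y_px[j])^2)
    same <- gaze$trial_id[i] == gaze$trial_id[j]
    if (same && dt > 0 && dt <= max_gap_ms && dist / dt <= velocity_threshold) {
      cur <- c(cur, i)
    } else {
      flush(cur); cur <- i
    }
  }
  flush(cur)
  for (r in runs) {
    if (length(r) < 2) next
    t <- gaze$t_ms[r]
    dur <- t[length(t)] - t[1]
    if (dur < min_duration_ms) next
    d_prev <- c(0, diff(t)); d_next <- c(diff(t), 0)
    w <- (d_prev + d_next) / 2
    out[[length(out) + 1]] <- data.frame(
      trial_id = gaze$trial_id[r[1]], start_ms = t[1], end_ms = t[length(t)],
      duration_ms = dur,
      centroid_x_px = sum(w * gaze$x_px[r]) / sum(w),
      centroid_y_px = sum(w * gaze$y_px[r]) / sum(w),
      n_samples = length(r), stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(detect_fixations(gaze[0, , drop = FALSE]))
  }
  do.call(rbind, out)
}

# Random gaze stream with saccades, invalid stretches and timing gaps, for
# detector/oracle agreement checks.
random_stream <- function(seed, n_trials = 3, n_per_trial = 60) {
  set.seed(seed)
  rows <- lapply(seq_len(n_trials), function(tr) {
    t <- cumsum(sample(c(16, 17, 40, 120), n_per_trial, replace = TRUE,
                       prob = c(0.45, 0.35, 0.12, 0.08)))
    x <- numeric(n_per_trial); y <- numeric(n_per_trial)
    cx <- runif(1, 100, 1100); cy <- runif(1, 100, 900)
    for (i in seq_len(n_per_trial)) {
      if (runif(1) < 0.08) { cx <- runif(1, 100, 1100); cy <- runif(1, 100, 900) }
      x[i] <- cx + rnorm(1, 0, 4); y[i] <- cy + rnorm(1, 0, 4)
    }
    data.frame(trial_id = sprintf("T%02d", tr), t_ms = t, x_px = x, y_px = y,
               valid = runif(n_per_trial) > 0.07, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Small clean dataset used by several files.
quick_dataset <- function(seed = 101, ...) {
  simulate_gaze(gen_config(n_subjects = 2, sessions_per_subject = 2,
                           trials_per_session = 10, missing_trial_prob = 0,
                           overrun_prob = 0, center_absent_prob = 0,
                           seed = seed, ...))
}
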