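#' Simulate a preferential-looking gaze dataset
#'
#' Generates raw two-ROI gaze streams, a trial manifest and a ground-truth
#' record under the zero-one-inflated beta generative model described in
#' [gen_config()]. Each trial consists of a pre-stimulus centre-fixation
#' window (-3000..0 ms, mirroring a 3 s fixation video) followed by the
#' stimulus window, during which the simulated subject alternates dwells
#' between the two scene ROIs so that the realized dwell split matches the
#' trial's latent dwell proportion. Calibration drift, missing-gaze trials,
#' overrunning final fixations and absent centre fixations are injected at
#' the configured rates.
#'
#' All randomness derives from `config$seed`; two calls with the same
#' config produce identical output, and the caller's RNG state is left
#' untouched. Horizontal drift is applied as a post-hoc coordinate shift,
#' so a drifted and an undrifted run of the same config differ only by
#' that shift.
#'
#' @param config A [gen_config()].
#' @param geometry A [screen_geometry()].
#' @param emit_gaze If `FALSE`, skip raw sample emission and return only the
#'   manifest and ground truth (realized dwell times then come from the
#'   planned dwell segments rather than the emitted sample grid); used for
#'   fast calibration studies of the inference stage.
#' @return An object of class `"gaze_dataset"`: a list with
#'   \describe{
#'     \item{gaze}{data.frame `trial_id, t_ms, x_px, y_px, valid` (absent
#'       columns-wise if `emit_gaze = FALSE`).}
#'     \item{manifest}{data.frame `trial_id, subject, session,
#'       species_on_scene, emotion_category, emotional_side,
#'       stimulus_pair_id`.}
#'     \item{truth}{data.frame of per-trial latent and realized values:
#'       `mu`, `y_latent`, `inflated`, `tfd_emotional_ms`,
#'       `tfd_neutral_ms`, `y_realized`, nuisance flags, random intercepts
#'       and the applied drift.}
#'     \item{geometry, config}{echoes of the inputs.}
#'   }
#' @examples
#' ds <- simulate_gaze(gen_config(n_subjects = 1, sessions_per_subject = 1,
#'                                trials_per_session = 4, seed = 42))
#' head(ds$gaze)
#' @export
simulate_gaze <- function(config, geometry = screen_geometry(),
                          emit_gaze = TRUE) {
  stopifnot(inherits(config, "gen_config"), inherits(geometry, "screen_geometry"))
  validate_gen_config(config)
  with_seed(config$seed, simulate_gaze_impl(config, geometry, emit_gaze))
}

simulate_gaze_impl <- function(cfg, geom, emit_gaze) {
  conds <- names(default_bias())
  bias <- default_bias() * 0 + 0.5
  bias[names(cfg$bias_by_condition)] <- cfg$bias_by_condition

  b_subj <- stats::rnorm(cfg$n_subjects, 0, cfg$subject_sd)
  b_sess <- matrix(stats::rnorm(cfg$n_subjects * cfg$sessions_per_subject,
                                0, cfg$session_sd),
                   nrow = cfg$n_subjects)

  # --- manifest: conditions balanced and side counterbalanced per session
  man <- vector("list", cfg$n_subjects * cfg$sessions_per_subject)
  idx <- 0L
  for (s in seq_len(cfg$n_subjects)) {
    for (j in seq_len(cfg$sessions_per_subject)) {
      idx <- idx + 1L
      tc <- sample(rep_len(conds, cfg$trials_per_session))
      sd_ <- sample(rep_len(c("left", "right"), cfg$trials_per_session))
      sp <- sub("\\..*$", "", tc)
      em <- sub("^[^.]*\\.", "", tc)
      man[[idx]] <- data.frame(
        trial_id = sprintf("S%02d_s%02d_t%02d", s, j,
                           seq_len(cfg$trials_per_session)),
        subject = sprintf("S%02d", s),
        session = j,
        species_on_scene = sp,
        emotion_category = em,
        emotional_side = sd_,
        stimulus_pair_id = paste0(sp, "_", em, "_p",
                                  stats::ave(seq_along(tc), tc, FUN = seq_along)),
        stringsAsFactors = FALSE
      )
    }
  }
  manifest <- do.call(rbind, man)
  rownames(manifest) <- NULL
  n_tr <- nrow(manifest)

  # --- latent trial values
  subj_i <- as.integer(sub("^S", "", manifest$subject))
  eta <- stats::qlogis(bias[paste(manifest$species_on_scene,
                                  manifest$emotion_category, sep = ".")]) +
    b_subj[subj_i] + b_sess[cbind(subj_i, manifest$session)]
  mu <- stats::plogis(eta)
  inflated <- stats::runif(n_tr) < cfg$zoi_prob
  one <- stats::runif(n_tr) < cfg$coi_prob
  y_beta <- stats::rbeta(n_tr, mu * cfg$precision_phi,
                         (1 - mu) * cfg$precision_phi)
  y <- ifelse(inflated, as.numeric(one), y_beta)
  missing <- stats::runif(n_tr) < cfg$missing_trial_prob
  overrun <- stats::runif(n_tr) < cfg$overrun_prob
  center_present <- stats::runif(n_tr) >= cfg$center_absent_prob

  lc <- rect_center(geom$left_roi)
  rc <- rect_center(geom$right_roi)
  cc <- rect_center(geom$center_roi)

  acc <- list(trial = character(0), t = numeric(0), x = numeric(0),
              y = numeric(0))
  gx <- gy <- gt <- gid <- vector("list", n_tr)
  tfd_e <- tfd_n <- numeric(n_tr)

  for (i in seq_len(n_tr)) {
    segs <- plan_trial(y[i], cfg, missing[i], overrun[i], center_present[i])
    stim <- segs[segs$kind %in% c("emo", "neu"), , drop = FALSE]
    if (emit_gaze) {
      out <- emit_trial_samples(segs, manifest$emotional_side[i], cfg, geom,
                                lc, rc, cc)
      gid[[i]] <- rep(manifest$trial_id[i], length(out$t))
      gt[[i]] <- out$t; gx[[i]] <- out$x; gy[[i]] <- out$y
      tfd_e[i] <- out$tfd_e; tfd_n[i] <- out$tfd_n
    } else {
      dur <- stim$end - stim$start
      tfd_e[i] <- sum(dur[stim$kind == "emo"])
      tfd_n[i] <- sum(dur[stim$kind == "neu"])
    }
  }

  truth <- data.frame(
    trial_id = manifest$trial_id,
    subject = manifest$subject,
    session = manifest$session,
    species_on_scene = manifest$species_on_scene,
    emotion_category = manifest$emotion_category,
    emotional_side = manifest$emotional_side,
    mu = unname(mu),
    y_latent = y,
    inflated = inflated,
    tfd_emotional_ms = tfd_e,
    tfd_neutral_ms = tfd_n,
    y_realized = ifelse(tfd_e + tfd_n > 0, tfd_e / (tfd_e + tfd_n), NA_real_),
    missing = missing,
    overrun = overrun,
    center_present = center_present,
    b_subject = b_subj[subj_i],
    b_session = b_sess[cbind(subj_i, manifest$session)],
    drift_px = drift_for_session(cfg, manifest$session),
    stringsAsFactors = FALSE
  )

  gaze <- NULL
  if (emit_gaze) {
    gaze <- data.frame(
      trial_id = unlist(gid, use.names = FALSE) %||% character(0),
      t_ms = unlist(gt, use.names = FALSE) %||% numeric(0),
      x_px = unlist(gx, use.names = FALSE) %||% numeric(0),
      y_px = unlist(gy, use.names = FALSE) %||% numeric(0),
      valid = TRUE,
      stringsAsFactors = FALSE
    )
    # post-hoc horizontal calibration drift, constant within session
    drift <- drift_for_session(cfg,
                               manifest$session[match(gaze$trial_id,
                                                      manifest$trial_id)])
    gaze$x_px <- gaze$x_px + drift
  }

  structure(list(gaze = gaze, manifest = manifest, truth = truth,
                 geometry = geom, config = cfg),
            class = "gaze_dataset")
}

drift_for_session <- function(cfg, session) {
  d <- cfg$drift_px_by_session
  if (length(d) == 0) return(rep(0, length(session)))
  out <- d[as.character(session)]
  out[is.na(out)] <- 0
  unname(out)
}

# Plan the dwell segments of one trial (times in ms relative to stimulus
# onset; stimulus window is [0, trial_duration]). Returns a data.frame with
# columns start, end, kind in {center, away, emo, neu}. Dwells alternate
# between the two scenes with 20-60 ms saccade gaps; planned dwell times are
# adjusted so that every emitted dwell is at least GB_MIN_DWELL_MS long.
plan_trial <- function(y, cfg, missing, overrun, center_present) {
  trial_ms <- cfg$trial_duration_s * 1000
  pre <- data.frame(
    start = c(-2800, -600), end = c(-2100, -60),
    kind = c("center", if (center_present) "center" else "away"),
    stringsAsFactors = FALSE
  )
  delay <- stats::runif(1, GB_ONSET_DELAY_MS[1], GB_ONSET_DELAY_MS[2])
  tot <- stats::rnorm(1, cfg$total_look_mean_s * 1000,
                      cfg$total_look_sd_s * 1000)
  tot <- min(max(tot, 4 * GB_MIN_DWELL_MS), trial_ms - delay - 3 * GB_GAP_MS[2])
  e_ms <- y * tot
  n_ms <- tot - e_ms
  if (e_ms > 0 && e_ms < GB_MIN_DWELL_MS) { e_ms <- GB_MIN_DWELL_MS; n_ms <- tot - e_ms }
  if (n_ms > 0 && n_ms < GB_MIN_DWELL_MS) { n_ms <- GB_MIN_DWELL_MS; e_ms <- tot - n_ms }

  split2 <- function(total) {
    w <- stats::runif(1)
    p1 <- GB_MIN_DWELL_MS + w * (total - 2 * GB_MIN_DWELL_MS)
    c(p1, total - p1)
  }
  k_e <- if (e_ms <= 0) 0L else if (e_ms >= 2 * GB_MIN_DWELL_MS &&
                                    n_ms > 0 && tot >= 1600) 2L else 1L
  k_n <- if (n_ms <= 0) 0L else if (n_ms >= 2 * GB_MIN_DWELL_MS &&
                                    e_ms > 0 && tot >= 1600) 2L else 1L
  e_parts <- if (k_e == 2L) split2(e_ms) else if (k_e == 1L) e_ms else numeric(0)
  n_parts <- if (k_n == 2L) split2(n_ms) else if (k_n == 1L) n_ms else numeric(0)

  # interleave, randomizing which scene is looked at first
  emo_first <- stats::runif(1) < 0.5
  a <- if (emo_first) list(d = e_parts, k = "emo") else list(d = n_parts, k = "neu")
  b <- if (emo_first) list(d = n_parts, k = "neu") else list(d = e_parts, k = "emo")
  durs <- numeric(0); kinds <- character(0)
  for (r in seq_len(max(length(a$d), length(b$d)))) {
    if (r <= length(a$d)) { durs <- c(durs, a$d[r]); kinds <- c(kinds, a$k) }
    if (r <= length(b$d)) { durs <- c(durs, b$d[r]); kinds <- c(kinds, b$k) }
  }
  n_seg <- length(durs)
  if (n_seg == 0 || missing) return(pre)

  gaps <- if (n_seg > 1) stats::runif(n_seg - 1, GB_GAP_MS[1], GB_GAP_MS[2]) else numeric(0)
  starts <- delay + cumsum(c(0, durs[-n_seg] + gaps))
  ends <- starts + durs
  if (overrun) {
    # tracker keeps reporting the final fixation past stimulus offset
    target <- max(trial_ms + 200, tot + 400, stats::rnorm(1, 4600, 1100))
    ends[n_seg] <- ends[n_seg] + (target - tot)
  }
  rbind(pre, data.frame(start = starts, end = ends, kind = kinds,
                        stringsAsFactors = FALSE))
}

# Emit gaze samples on the eye-tracker sampling grid for every planned
# segment; returns sample vectors plus realized per-scene dwell times
# measured as the sample span of each stimulus dwell (exactly what a
# fixation detector operating on these samples can recover).
emit_trial_samples <- function(segs, emotional_side, cfg, geom, lc, rc, cc) {
  p <- 1000 / cfg$sample_rate_hz
  t <- x <- yv <- vector("list", nrow(segs))
  tfd_e <- tfd_n <- 0
  for (k in seq_len(nrow(segs))) {
    i0 <- ceiling(segs$start[k] / p - 1e-9)
    i1 <- floor(segs$end[k] / p + 1e-9)
    if (i1 < i0) next
    tk <- round((i0:i1) * p)
    kind <- segs$kind[k]
    ctr <- switch(kind,
      center = cc,
      away = c(x = 80, y = 80),
      emo = if (emotional_side == "left") lc else rc,
      neu = if (emotional_side == "left") rc else lc
    )
    roi <- switch(kind, center = geom$center_roi, away = NULL,
                  emo = if (emotional_side == "left") geom$left_roi else geom$right_roi,
                  neu = if (emotional_side == "left") geom$right_roi else geom$left_roi)
    off <- stats::rnorm(2, 0, if (kind %in% c("emo", "neu")) 25 else 8)
    cx <- ctr[["x"]] + off[1]; cy <- ctr[["y"]] + off[2]
    if (!is.null(roi)) {
      margin <- 50
      cx <- min(max(cx, roi[["x0"]] + margin), roi[["x1"]] - margin)
      cy <- min(max(cy, roi[["y0"]] + margin), roi[["y1"]] - margin)
    }
    n <- length(tk)
    t[[k]] <- tk
    x[[k]] <- cx + stats::rnorm(n, 0, cfg$noise_sd_px)
    yv[[k]] <- cy + stats::rnorm(n, 0, cfg$noise_sd_px)
    if (kind %in% c("emo", "neu") && n >= 2) {
      span <- tk[n] - tk[1]
      if (kind == "emo") tfd_e <- tfd_e + span else tfd_n <- tfd_n + span
    }
  }
  list(t = unlist(t), x = unlist(x), y = unlist(yv),
       tfd_e = tfd_e, tfd_n = tfd_n)
}

#' @export
print.gaze_dataset <- function(x, ...) {
  cat(sprintf("gaze_dataset: %d trials, %d subjects, %s gaze samples\n",
              nrow(x$manifest), length(unique(x$manifest$subject)),
              if (is.null(x$gaze)) "no" else format(nrow(x$gaze), big.mark = ",")))
  invisible(x)
}
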