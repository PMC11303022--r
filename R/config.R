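#' Emotion categories and scene species used by the paradigm
#'
#' @return Character vectors of factor levels.
#' @export
emotion_levels <- function() {
  c("distress", "groom_embrace", "play", "sex_erotic", "yawn")
}

#' @rdname emotion_levels
#' @export
species_levels <- function() c("bonobo", "human")

default_bias <- function() {
  # Condition means of the dwell proportion on the emotional scene,
  # emulating a modest conspecific emotional-attention bias: slightly above
  # chance for conspecific scenes, slightly below for heterospecific ones.
  conds <- as.vector(outer(species_levels(), emotion_levels(), paste, sep = "."))
  stats::setNames(ifelse(startsWith(conds, "bonobo"), 0.52, 0.48), conds)
}

#' Generative configuration for the synthetic-gaze simulator
#'
#' Bundles every knob of the trial generator: the experimental design
#' (subjects, sessions, trials), the zero-one-inflated beta (ZOIB) model
#' that produces latent dwell proportions, and the nuisance processes the
#' preprocessing stage must survive (calibration drift, missing-gaze
#' trials, fixations overrunning stimulus offset, absent pre-stimulus
#' centre fixations).
#'
#' The latent dwell proportion of a trial in condition `c` (a
#' `species.emotion` cell) is drawn as: with probability `zoi_prob` an
#' inflated value (1 with probability `coi_prob`, else 0); otherwise
#' `Beta(mu * phi, (1 - mu) * phi)` with
#' `logit(mu) = logit(bias_by_condition[c]) + b_subject + b_session`,
#' where the random intercepts have standard deviations `subject_sd` and
#' `session_sd` on the logit scale.
#'
#' @param n_subjects,sessions_per_subject,trials_per_session Design sizes.
#' @param sample_rate_hz Eye-tracker sampling rate (Hz).
#' @param trial_duration_s Stimulus presentation length (seconds).
#' @param bias_by_condition Named vector of mean emotional-dwell proportions,
#'   names `"species.emotion"`; missing cells fall back to 0.5.
#' @param zoi_prob Probability a trial's dwell proportion is exactly 0 or 1.
#' @param coi_prob Conditional probability the inflated value is 1.
#' @param precision_phi Beta precision (> 0).
#' @param subject_sd,session_sd Random-intercept SDs, logit scale.
#' @param drift_px_by_session Named numeric vector, session number to
#'   horizontal calibration offset in pixels (applied to all gaze of that
#'   session); empty means no drift.
#' @param missing_trial_prob Probability a trial yields no stimulus-window gaze.
#' @param overrun_prob Probability the final fixation extends past stimulus
#'   offset, producing an unclipped fixation total above `trial_duration_s`.
#' @param center_absent_prob Probability the pre-stimulus centre fixation is
#'   absent during the final 500 ms before onset (the subject looked away).
#' @param noise_sd_px Isotropic gaze jitter SD within a dwell, pixels.
#' @param total_look_mean_s,total_look_sd_s Mean and SD of the per-trial
#'   total looking time on the two scenes (seconds), truncated to fit the
#'   trial.
#' @param seed Integer seed; all randomness in [simulate_gaze()] derives
#'   from it.
#' @return An object of class `"gen_config"` (validated list).
#' @examples
#' cfg <- gen_config(n_subjects = 2, sessions_per_subject = 2, seed = 7)
#' @export
gen_config <- function(n_subjects = 4L,
                       sessions_per_subject = 12L,
                       trials_per_session = 10L,
                       sample_rate_hz = 60,
                       trial_duration_s = 3,
                       bias_by_condition = default_bias(),
                       zoi_prob = 0.10,
                       coi_prob = 0.5,
                       precision_phi = 10,
                       subject_sd = 0.20,
                       session_sd = 0.10,
                       drift_px_by_session = numeric(0),
                       missing_trial_prob = 0.097,
                       overrun_prob = 0.01,
                       center_absent_prob = 0.10,
                       noise_sd_px = 5,
                       total_look_mean_s = 2.0,
                       total_look_sd_s = 0.6,
                       seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    sessions_per_subject = as.integer(sessions_per_subject),
    trials_per_session = as.integer(trials_per_session),
    sample_rate_hz = sample_rate_hz,
    trial_duration_s = trial_duration_s,
    bias_by_condition = bias_by_condition,
    zoi_prob = zoi_prob, coi_prob = coi_prob,
    precision_phi = precision_phi,
    subject_sd = subject_sd, session_sd = session_sd,
    drift_px_by_session = drift_px_by_session,
    missing_trial_prob = missing_trial_prob,
    overrun_prob = overrun_prob,
    center_absent_prob = center_absent_prob,
    noise_sd_px = noise_sd_px,
    total_look_mean_s = total_look_mean_s,
    total_look_sd_s = total_look_sd_s,
    seed = as.integer(seed)
  )
  class(cfg) <- "gen_config"
  validate_gen_config(cfg)
}

validate_gen_config <- function(cfg) {
  probs <- c(zoi_prob = cfg$zoi_prob, coi_prob = cfg$coi_prob,
             missing_trial_prob = cfg$missing_trial_prob,
             overrun_prob = cfg$overrun_prob,
             center_absent_prob = cfg$center_absent_prob,
             cfg$bias_by_condition)
  if (any(probs < 0 | probs > 1)) {
    stop_gb("probabilities must lie in [0, 1]; offending: %s",
            paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  }
  if (!is.finite(cfg$precision_phi) || cfg$precision_phi <= 0)
    stop_gb("precision_phi must be > 0")
  if (cfg$sample_rate_hz <= 0) stop_gb("sample_rate_hz must be > 0")
  if (any(c(cfg$n_subjects, cfg$sessions_per_subject,
            cfg$trials_per_session) < 1))
    stop_gb("design counts must be >= 1")
  if (any(c(cfg$subject_sd, cfg$session_sd, cfg$noise_sd_px,
            cfg$total_look_sd_s) < 0))
    stop_gb("standard deviations must be >= 0")
  # the dwell plan needs room for an onset delay, two minimum-length dwells
  # and a saccade gap inside the stimulus window
  min_ms <- GB_ONSET_DELAY_MS[1] + 2 * GB_MIN_DWELL_MS + GB_GAP_MS[2]
  if (cfg$trial_duration_s * 1000 < min_ms) {
    stop_gb("trial_duration_s = %g s cannot fit the ROI dwell geometry (needs >= %g ms)",
            cfg$trial_duration_s, min_ms)
  }
  cfg
}

# dwell-plan constants (ms)
GB_MIN_DWELL_MS <- 100
GB_GAP_MS <- c(20, 60)
GB_ONSET_DELAY_MS <- c(100, 400)

#' @export
print.gen_config <- function(x, ...) {
  cat(sprintf("gen_config: %d subjects x %d sessions x %d trials (seed %d)\n",
              x$n_subjects, x$sessions_per_subject, x$trials_per_session,
              x$seed))
  cat(sprintf("  ZOIB: phi = %g, zoi = %g, coi = %g; subject_sd = %g, session_sd = %g\n",
              x$precision_phi, x$zoi_prob, x$coi_prob, x$subject_sd,
              x$session_sd))
  cat(sprintf("  nuisance: missing %g, overrun %g, center-absent %g, drifted sessions %d\n",
              x$missing_trial_prob, x$overrun_prob, x$center_absent_prob,
              length(x$drift_px_by_session)))
  invisible(x)
}
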