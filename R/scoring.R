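#' Proportional looking duration for the emotional scene
#'
#' `PLD_emotion = TFD_emotional / (TFD_emotional + TFD_neutral)`: the share
#' of a trial's scene-directed looking spent on the emotional scene. Values
#' above 0.5 indicate longer looking at the emotional scene. Vectorized;
#' trials with no looking on either scene yield `NA` (such trials are
#' routed to the `no_gaze` exclusion by [filter_tfd()], never scored).
#'
#' @param tfd_emotional_s,tfd_neutral_s Per-scene total fixation durations
#'   (seconds), both `>= 0`.
#' @return Proportion in `[0, 1]`, or `NA` where both inputs are zero.
#' @examples
#' pld_emotion(1.2, 0.8)  # 0.6
#' @export
pld_emotion <- function(tfd_emotional_s, tfd_neutral_s) {
  if (any(tfd_emotional_s < 0, na.rm = TRUE) ||
      any(tfd_neutral_s < 0, na.rm = TRUE)) {
    stop_gb("fixation durations must be >= 0")
  }
  tot <- tfd_emotional_s + tfd_neutral_s
  ifelse(tot > 0, tfd_emotional_s / tot, NA_real_)
}

#' Attention weight of a trial
#'
#' `weight = total looking in the trial / subject's mean total looking
#' over included trials`. Weighted inference thereby gives more importance
#' to trials in which the subject attended more to the scenes; by
#' construction the weights of each subject's included trials average 1.
#'
#' @param trial_total_s Total scene looking of the trial (seconds).
#' @param subject_mean_total_s The subject's mean of `trial_total_s` over
#'   included trials (> 0).
#' @return Positive ratio.
#' @export
trial_weight <- function(trial_total_s, subject_mean_total_s) {
  if (any(subject_mean_total_s <= 0)) {
    stop_gb("subject mean looking time must be > 0 (no included trials?)")
  }
  trial_total_s / subject_mean_total_s
}

#' First-fixation location from per-scene latencies
#'
#' Binarizes immediate attention: 1 when the emotional scene is fixated
#' first (strictly shorter latency), 0 when the neutral scene is; if only
#' one scene was ever fixated, that scene wins. Exact latency ties (possible
#' on the sampling grid) are unresolvable and yield `NA`, which
#' [filter_ttff()] excludes under `tie_or_single_roi`.
#'
#' @param ttff_emotional_ms,ttff_neutral_ms Latencies (ms), `NA` when the
#'   scene was never fixated.
#' @return Integer vector in `{0, 1, NA}`.
#' @examples
#' first_fixation_location(200, 450)  # 1
#' @export
first_fixation_location <- function(ttff_emotional_ms, ttff_neutral_ms) {
  e <- ttff_emotional_ms; n <- ttff_neutral_ms
  out <- rep(NA_integer_, length(e))
  out[!is.na(e) & is.na(n)] <- 1L
  out[is.na(e) & !is.na(n)] <- 0L
  both <- !is.na(e) & !is.na(n)
  out[both & e < n] <- 1L
  out[both & e > n] <- 0L
  out  # both & e == n stays NA (tie)
}

new_ledger <- function(measure, total, removed) {
  stopifnot(total - sum(removed) >= 0)
  structure(list(measure = measure, total = total,
                 removed_by_reason = as.list(removed),
                 valid = total - sum(removed),
                 pct_removed = round(100 * sum(removed) / total, 1),
                 pct_valid = round(100 * (total - sum(removed)) / total, 1)),
            class = "exclusion_ledger")
}

#' @export
print.exclusion_ledger <- function(x, ...) {
  cat(sprintf("%s exclusion ledger: %d trials\n", x$measure, x$total))
  for (r in names(x$removed_by_reason)) {
    cat(sprintf("  - %-22s %5d\n", r, x$removed_by_reason[[r]]))
  }
  cat(sprintf("  valid: %d (%.1f%%; %.1f%% removed)\n",
              x$valid, x$pct_valid, x$pct_removed))
  if (!is.null(x$pre_exclusion_total)) {
    cat(sprintf("  of pre-exclusion total %d: %.1f%% valid\n",
                x$pre_exclusion_total,
                100 * x$valid / x$pre_exclusion_total))
  }
  invisible(x)
}

check_manifest_match <- function(metrics, manifest) {
  orphan_m <- setdiff(metrics$trial_id, manifest$trial_id)
  orphan_f <- setdiff(manifest$trial_id, metrics$trial_id)
  if (length(orphan_m) || length(orphan_f)) {
    stop_gb("metrics/manifest mismatch; orphan trials: %s",
            paste(utils::head(c(orphan_m, orphan_f), 10), collapse = ", "))
  }
}

covar_cols <- c("subject", "session", "species_on_scene", "emotion_category",
                "emotional_side")

#' Score sustained attention: validity filter, PLD and weights
#'
#' Applies the sustained-attention (TFD) validity rules sequentially —
#' each trial is counted once, under the first rule it triggers:
#' \enumerate{
#'   \item `no_gaze`: no fixation on either scene ROI during the stimulus
#'     window;
#'   \item `overrun`: the tracker-reported (unclipped) fixation total
#'     exceeds the stimulus presentation time, indicating a fixation that
#'     ran past stimulus offset.
#' }
#' Remaining trials are scored with [pld_emotion()] and [trial_weight()];
#' subject means for the weights are computed over included trials only.
#'
#' @param metrics Per-trial metrics from [compute_metrics()].
#' @param manifest Trial manifest (one row per metrics trial).
#' @param overrun_limit_s Unclipped-total threshold (seconds).
#' @param overrun_rule `"summed"` tests the summed unclipped total over
#'   both ROIs (default); `"per_roi"` tests each ROI's total separately.
#' @return List with `scored` (data.frame: trial_id, design covariates,
#'   `total_look_s`, `pld_emotion`, `weight`, `excluded`, `reason`) and
#'   `ledger` (an exclusion ledger; `valid = total - sum(removed)`).
#' @export
filter_tfd <- function(metrics, manifest, overrun_limit_s = 3,
                       overrun_rule = c("summed", "per_roi")) {
  overrun_rule <- match.arg(overrun_rule)
  check_manifest_match(metrics, manifest)
  man <- manifest[match(metrics$trial_id, manifest$trial_id), , drop = FALSE]

  no_gaze <- !metrics$any_gaze
  over <- if (overrun_rule == "summed") {
    metrics$tfd_left_unclipped_s + metrics$tfd_right_unclipped_s > overrun_limit_s
  } else {
    pmax(metrics$tfd_left_unclipped_s, metrics$tfd_right_unclipped_s) > overrun_limit_s
  }
  reason <- rep(NA_character_, nrow(metrics))
  reason[over] <- "overrun"
  reason[no_gaze] <- "no_gaze"  # sequential: no_gaze takes precedence

  emo_left <- man$emotional_side == "left"
  tfd_emo <- ifelse(emo_left, metrics$tfd_left_s, metrics$tfd_right_s)
  tfd_neu <- ifelse(emo_left, metrics$tfd_right_s, metrics$tfd_left_s)

  scored <- data.frame(trial_id = metrics$trial_id,
                       man[, intersect(covar_cols, names(man)), drop = FALSE],
                       total_look_s = tfd_emo + tfd_neu,
                       pld_emotion = pld_emotion(tfd_emo, tfd_neu),
                       weight = NA_real_,
                       excluded = !is.na(reason),
                       reason = reason,
                       row.names = NULL, stringsAsFactors = FALSE)
  inc <- !scored$excluded
  if (any(inc)) {
    subj_mean <- tapply(scored$total_look_s[inc], scored$subject[inc], mean)
    scored$weight[inc] <- trial_weight(scored$total_look_s[inc],
                                       as.numeric(subj_mean[scored$subject[inc]]))
  }
  removed <- c(no_gaze = sum(reason == "no_gaze", na.rm = TRUE),
               overrun = sum(reason == "overrun", na.rm = TRUE))
  list(scored = scored, ledger = new_ledger("TFD", nrow(metrics), removed))
}

#' Score immediate attention: validity filter and first-fixation location
#'
#' Applies the immediate-attention (TTFF) validity rules sequentially.
#' In `species_mode = "bonobo"` the first rule follows the primate
#' protocol: a trial is removed (`center_fail_or_short`) when the subject's
#' gaze was not on the centre fixation video during the final
#' `center_window_ms` before onset *or* the earliest scene latency is
#' anticipatorily short (`< min_latency_ms`) — both symptoms that attention
#' was already off-centre at onset. In `species_mode = "human"` only the
#' short-latency test is applied. Then `no_data` removes trials where no
#' scene was ever fixated, and `tie_or_single_roi` removes exact latency
#' ties. Remaining trials are binarized with [first_fixation_location()].
#'
#' @inheritParams filter_tfd
#' @param min_latency_ms Anticipatory-latency threshold (ms).
#' @param species_mode `"bonobo"` or `"human"` filter variant.
#' @param pre_exclusion_total Optional count of trials before upstream
#'   removals (echoed in the ledger so percentages can be reported against
#'   either denominator).
#' @return List with `scored` (trial_id, covariates,
#'   `first_fix_emotional`, `excluded`, `reason`) and `ledger`.
#' @export
filter_ttff <- function(metrics, manifest, min_latency_ms = 80,
                        species_mode = c("bonobo", "human"),
                        pre_exclusion_total = NULL) {
  species_mode <- match.arg(species_mode)
  check_manifest_match(metrics, manifest)
  man <- manifest[match(metrics$trial_id, manifest$trial_id), , drop = FALSE]

  ttff_min <- suppressWarnings(pmin(metrics$ttff_left_ms, metrics$ttff_right_ms,
                                    na.rm = TRUE))
  ttff_min[is.infinite(ttff_min)] <- NA_real_
  short <- !is.na(ttff_min) & ttff_min < min_latency_ms
  fail1 <- if (species_mode == "bonobo") (!metrics$center_ok) | short else short
  no_data <- is.na(metrics$ttff_left_ms) & is.na(metrics$ttff_right_ms)

  emo_left <- man$emotional_side == "left"
  ttff_emo <- ifelse(emo_left, metrics$ttff_left_ms, metrics$ttff_right_ms)
  ttff_neu <- ifelse(emo_left, metrics$ttff_right_ms, metrics$ttff_left_ms)
  ff <- first_fixation_location(ttff_emo, ttff_neu)
  tie <- is.na(ff) & !no_data

  reason <- rep(NA_character_, nrow(metrics))
  reason[tie] <- "tie_or_single_roi"
  reason[no_data] <- "no_data"
  reason[fail1] <- "center_fail_or_short"  # first rule wins

  scored <- data.frame(trial_id = metrics$trial_id,
                       man[, intersect(covar_cols, names(man)), drop = FALSE],
                       first_fix_emotional = ifelse(is.na(reason), ff, NA_integer_),
                       excluded = !is.na(reason),
                       reason = reason,
                       row.names = NULL, stringsAsFactors = FALSE)
  removed <- c(center_fail_or_short = sum(reason == "center_fail_or_short",
                                          na.rm = TRUE),
               no_data = sum(reason == "no_data", na.rm = TRUE),
               tie_or_single_roi = sum(reason == "tie_or_single_roi",
                                       na.rm = TRUE))
  ledger <- new_ledger("TTFF", nrow(metrics), removed)
  if (!is.null(pre_exclusion_total)) {
    ledger$pre_exclusion_total <- pre_exclusion_total
    ledger$pct_valid_of_pre_total <- round(100 * ledger$valid /
                                             pre_exclusion_total, 1)
  }
  list(scored = scored, ledger = ledger)
}

#' Write an exclusion ledger to JSON
#'
#' @param ledger An exclusion ledger from [filter_tfd()] or [filter_ttff()].
#' @param path File path.
#' @export
write_ledger <- function(ledger, path) {
  jsonlite::write_json(unclass(ledger), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
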