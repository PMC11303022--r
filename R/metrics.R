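#' Per-trial ROI looking metrics
#'
#' Computes, for every manifest trial, the Total Fixation Duration (TFD)
#' and Time To First Fixation (TTFF) on each scene ROI plus the validity
#' flags the downstream filters need. A fixation belongs to an ROI when its
#' centroid lies inside the (half-open) rectangle. TFD is the summed
#' fixation time clipped to the stimulus window; the unclipped sums are
#' retained so the overrun filter can test the tracker-reported totals.
#' TTFF is the onset-to-start latency of the first fixation on the ROI that
#' overlaps the stimulus window (0 if the fixation was already ongoing at
#' onset). `center_ok` records whether some pre-stimulus fixation centroid
#' fell inside the centre ROI during the final `center_window_ms` before
#' onset; `any_gaze` whether any stimulus-window fixation hit either ROI.
#'
#' @param fixations Fixation data.frame from [detect_fixations()]; may span
#'   many trials.
#' @param geometry A [screen_geometry()].
#' @param trial_ids Trials to report (default: those present in
#'   `fixations`); trials without fixations yield `any_gaze = FALSE` rows.
#' @param stimulus_onset_ms Stimulus onset time (ms) in the log's clock.
#' @param stimulus_duration_s Stimulus presentation length (seconds).
#' @param center_window_ms Pre-onset window the centre check inspects (ms).
#' @return data.frame with one row per trial: `trial_id`, `tfd_left_s`,
#'   `tfd_right_s`, `tfd_left_unclipped_s`, `tfd_right_unclipped_s`,
#'   `ttff_left_ms`, `ttff_right_ms` (NA when the ROI is never fixated),
#'   `center_ok`, `any_gaze`.
#' @export
compute_metrics <- function(fixations, geometry, trial_ids = NULL,
                            stimulus_onset_ms = 0, stimulus_duration_s = 3,
                            center_window_ms = 500) {
  stopifnot(inherits(geometry, "screen_geometry"))
  if (is.null(trial_ids)) trial_ids <- unique(fixations$trial_id)
  w0 <- stimulus_onset_ms
  w1 <- stimulus_onset_ms + stimulus_duration_s * 1000

  out <- data.frame(trial_id = trial_ids,
                    tfd_left_s = 0, tfd_right_s = 0,
                    tfd_left_unclipped_s = 0, tfd_right_unclipped_s = 0,
                    ttff_left_ms = NA_real_, ttff_right_ms = NA_real_,
                    center_ok = FALSE, any_gaze = FALSE,
                    stringsAsFactors = FALSE)
  if (nrow(fixations) == 0) return(out)

  fx <- fixations[fixations$trial_id %in% trial_ids, , drop = FALSE]
  if (nrow(fx) == 0) return(out)
  row <- match(fx$trial_id, trial_ids)

  in_l <- in_rect(fx$centroid_x_px, fx$centroid_y_px, geometry$left_roi)
  in_r <- in_rect(fx$centroid_x_px, fx$centroid_y_px, geometry$right_roi)
  in_c <- in_rect(fx$centroid_x_px, fx$centroid_y_px, geometry$center_roi)

  clip <- pmax(0, pmin(fx$end_ms, w1) - pmax(fx$start_ms, w0))
  stim <- clip > 0
  ttff <- pmax(0, fx$start_ms - w0)

  add_roi <- function(out, roi_rows, tfd_col, unc_col, ttff_col) {
    rr <- which(roi_rows & stim)
    if (!length(rr)) return(out)
    tr <- row[rr]
    sums <- rowsum(cbind(clip[rr], fx$duration_ms[rr]), tr)  # sorted by trial row
    idx <- as.integer(rownames(sums))
    out[[tfd_col]][idx] <- sums[, 1] / 1000
    out[[unc_col]][idx] <- sums[, 2] / 1000
    first <- tapply(ttff[rr], tr, min)
    out[[ttff_col]][as.integer(names(first))] <- as.numeric(first)
    out
  }
  out <- add_roi(out, in_l, "tfd_left_s", "tfd_left_unclipped_s", "ttff_left_ms")
  out <- add_roi(out, in_r, "tfd_right_s", "tfd_right_unclipped_s", "ttff_right_ms")

  cen <- which(in_c & fx$end_ms > w0 - center_window_ms & fx$start_ms < w0)
  out$center_ok[unique(row[cen])] <- TRUE
  out$any_gaze <- out$tfd_left_s + out$tfd_right_s > 0 |
    !is.na(out$ttff_left_ms) | !is.na(out$ttff_right_ms)
  out
}

#' @rdname compute_metrics
#' @param trial_fixations Fixations of a single trial.
#' @export
compute_trial_metrics <- function(trial_fixations, geometry,
                                  stimulus_onset_ms = 0,
                                  stimulus_duration_s = 3,
                                  center_window_ms = 500) {
  ids <- unique(trial_fixations$trial_id)
  if (length(ids) > 1) stop_gb("expected fixations of a single trial")
  if (length(ids) == 0) ids <- "trial"
  compute_metrics(trial_fixations, geometry, trial_ids = ids,
                  stimulus_onset_ms = stimulus_onset_ms,
                  stimulus_duration_s = stimulus_duration_s,
                  center_window_ms = center_window_ms)
}
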