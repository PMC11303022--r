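#' Estimate a session's horizontal calibration offset by k-means
#'
#' In a two-stimulus session, fixation x-coordinates cluster around the two
#' ROI centres; a degraded calibration shifts both clusters by a common
#' horizontal offset. The estimator runs k-means (k = 2) on the
#' x-coordinates of the session's stimulus-window fixations, matches each
#' cluster centre to the nearest ROI centre-x, and reports the mean over
#' clusters of (ROI centre-x minus cluster centre): the signed number of
#' pixels to *add* to the session's gaze to realign it. The correction is
#' marked `applied` only when the magnitude reaches
#' `apply_threshold_px`, so well-calibrated sessions are left untouched.
#'
#' K-means is initialized deterministically from the 25% and 75% quantiles
#' of the x-coordinates, making the estimate a pure function of its inputs.
#'
#' @param fixations Fixation data.frame (one session) from
#'   [detect_fixations()]; only rows with `start_ms >= 0` (stimulus window)
#'   are used.
#' @param geometry A [screen_geometry()].
#' @param k Number of clusters (2: one per scene ROI).
#' @param apply_threshold_px Minimum |offset| for the correction to be
#'   applied, in pixels.
#' @param session Optional session label echoed in the result.
#' @return A one-row data.frame of class `"drift_estimate"`: `session`,
#'   `offset_px`, `n_fixations_used`, `applied`, `degenerate`.
#' @examples
#' ds <- simulate_gaze(gen_config(n_subjects = 1, sessions_per_subject = 1,
#'                                trials_per_session = 8,
#'                                drift_px_by_session = c("1" = -120),
#'                                seed = 5))
#' est <- estimate_session_offset(detect_fixations(ds$gaze), ds$geometry)
#' est$offset_px  # close to +120: the correction to add
#' @export
estimate_session_offset <- function(fixations, geometry, k = 2L,
                                    apply_threshold_px = 50,
                                    session = NA) {
  stopifnot(inherits(geometry, "screen_geometry"))
  stim <- fixations[fixations$start_ms >= 0, , drop = FALSE]
  res <- data.frame(session = session, offset_px = 0,
                    n_fixations_used = nrow(stim), applied = FALSE,
                    degenerate = FALSE, stringsAsFactors = FALSE)
  class(res) <- c("drift_estimate", "data.frame")
  if (nrow(stim) < 2L * k) {
    warn_gb("session %s: %d stimulus-window fixations (< %d); no drift estimated",
            as.character(session), nrow(stim), 2L * k)
    res$degenerate <- TRUE
    return(res)
  }
  xs <- stim$centroid_x_px
  if (diff(range(xs)) < 1e-8) {
    res$degenerate <- TRUE
    return(res)
  }
  centers <- matrix(stats::quantile(xs, probs = seq(0.25, 0.75,
                                                    length.out = k),
                                    names = FALSE), ncol = 1)
  if (any(diff(centers[, 1]) < 1e-8)) {
    centers[, 1] <- centers[, 1] + seq(0, 1e-6, length.out = k)
  }
  km <- suppressWarnings(stats::kmeans(xs, centers = centers))
  roi_cx <- c(rect_center(geometry$left_roi)[["x"]],
              rect_center(geometry$right_roi)[["x"]])
  nearest <- vapply(km$centers[, 1],
                    function(cx) which.min(abs(roi_cx - cx)), integer(1))
  if (length(unique(nearest)) < k) {
    # both clusters map to one ROI: subject only ever looked at one side
    res$degenerate <- TRUE
    return(res)
  }
  res$offset_px <- mean(roi_cx[nearest] - km$centers[, 1])
  res$applied <- abs(res$offset_px) >= apply_threshold_px
  res
}

#' Apply a horizontal offset to gaze samples or fixations
#'
#' Pure function: adds `offset_px` to every x-coordinate (`x_px` and/or
#' `centroid_x_px` column). Applying an offset and then its negation is the
#' identity.
#'
#' @param data Gaze or fixation data.frame.
#' @param offset_px Signed horizontal shift in pixels.
#' @return The corrected copy.
#' @export
apply_offset <- function(data, offset_px) {
  stopifnot(is.numeric(offset_px), length(offset_px) %in% c(1L, nrow(data)))
  if ("x_px" %in% names(data)) data$x_px <- data$x_px + offset_px
  if ("centroid_x_px" %in% names(data)) {
    data$centroid_x_px <- data$centroid_x_px + offset_px
  }
  data
}

#' Estimate and apply drift correction across all sessions
#'
#' Splits fixations by subject-session (via the manifest), estimates each
#' session's offset with [estimate_session_offset()], and corrects the
#' sessions whose |offset| reaches the threshold.
#'
#' @param fixations Fixation data.frame covering many trials.
#' @param manifest Trial manifest mapping `trial_id` to `subject`, `session`.
#' @param geometry A [screen_geometry()].
#' @param apply_threshold_px See [estimate_session_offset()].
#' @return List with `fixations` (corrected copy) and `report` (one row per
#'   subject-session: `subject`, `session`, `offset_px`,
#'   `n_fixations_used`, `applied`, `degenerate`).
#' @export
correct_drift <- function(fixations, manifest, geometry,
                          apply_threshold_px = 50) {
  key <- paste(manifest$subject, manifest$session, sep = ":")
  fix_key <- key[match(fixations$trial_id, manifest$trial_id)]
  if (anyNA(fix_key)) {
    stop_gb("fixations reference trials absent from the manifest: %s",
            paste(utils::head(unique(fixations$trial_id[is.na(fix_key)]), 5),
                  collapse = ", "))
  }
  reports <- list()
  shift <- numeric(nrow(fixations))
  for (kk in unique(key)) {
    rows <- which(fix_key == kk)
    est <- estimate_session_offset(fixations[rows, , drop = FALSE], geometry,
                                   apply_threshold_px = apply_threshold_px,
                                   session = kk)
    m <- match(kk, key)
    reports[[kk]] <- data.frame(subject = manifest$subject[m],
                                session = manifest$session[m],
                                offset_px = est$offset_px,
                                n_fixations_used = est$n_fixations_used,
                                applied = est$applied,
                                degenerate = est$degenerate,
                                stringsAsFactors = FALSE)
    if (est$applied) shift[rows] <- est$offset_px
  }
  list(fixations = apply_offset(fixations, shift),
       report = do.call(rbind, c(reports, list(make.row.names = FALSE))))
}
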