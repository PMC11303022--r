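#' Detect fixations with a velocity-threshold (I-VT style) filter
#'
#' Segments each trial's gaze stream into fixations: maximal runs of
#' consecutive valid samples whose point-to-point velocity stays below
#' `velocity_threshold_px_per_ms` and whose inter-sample gap does not
#' exceed `max_gap_ms`. Runs are broken by invalid samples, velocity
#' spikes (saccades) and tracking gaps. Runs lasting at least
#' `min_duration_ms` are emitted with their time-weighted centroid (each
#' sample weighted by half the interval to its neighbours, so the weights
#' sum to the run duration).
#'
#' @param gaze data.frame with `trial_id, t_ms, x_px, y_px, valid`; rows of
#'   one trial contiguous and time-ordered.
#' @param min_duration_ms Minimum fixation duration (ms).
#' @param velocity_threshold_px_per_ms Velocity above which a sample pair is
#'   treated as a saccade (px/ms).
#' @param max_gap_ms Largest tolerated gap between consecutive samples of a
#'   fixation (ms); larger gaps (blinks, track loss) end the run.
#' @return data.frame with columns `trial_id, start_ms, end_ms,
#'   duration_ms, centroid_x_px, centroid_y_px, n_samples`, one row per
#'   fixation, ordered as encountered. An empty stream yields zero rows.
#' @examples
#' ds <- simulate_gaze(gen_config(n_subjects = 1, sessions_per_subject = 1,
#'                                trials_per_session = 2, seed = 3))
#' fx <- detect_fixations(ds$gaze)
#' @export
detect_fixations <- function(gaze, min_duration_ms = 60,
                             velocity_threshold_px_per_ms = 3,
                             max_gap_ms = 75) {
  empty <- data.frame(trial_id = character(0), start_ms = numeric(0),
                      end_ms = numeric(0), duration_ms = numeric(0),
                      centroid_x_px = numeric(0), centroid_y_px = numeric(0),
                      n_samples = integer(0), stringsAsFactors = FALSE)
  if (is.null(gaze) || nrow(gaze) == 0) return(empty)
  stopifnot(all(c("trial_id", "t_ms", "x_px", "y_px", "valid") %in% names(gaze)))
  n <- nrow(gaze)
  t <- gaze$t_ms; x <- gaze$x_px; y <- gaze$y_px; v <- as.logical(gaze$valid)
  if (n == 1) {
    link <- logical(0)
  } else {
    same <- gaze$trial_id[-1] == gaze$trial_id[-n]
    dt <- diff(t)
    vel <- sqrt(diff(x)^2 + diff(y)^2) / pmax(dt, .Machine$double.eps)
    link <- same & v[-1] & v[-n] & dt > 0 & dt <= max_gap_ms &
      vel <= velocity_threshold_px_per_ms
  }
  run <- cumsum(c(TRUE, !link))
  keep <- v
  run <- run[keep]; t <- t[keep]; x <- x[keep]; y <- y[keep]
  tid <- gaze$trial_id[keep]
  if (length(run) == 0) return(empty)

  first <- !duplicated(run)
  last <- !duplicated(run, fromLast = TRUE)
  d_prev <- c(0, diff(t)); d_prev[first] <- 0
  d_next <- c(diff(t), 0); d_next[last] <- 0
  w <- (d_prev + d_next) / 2

  rf <- factor(run, levels = unique(run))
  sw <- rowsum(w, rf, reorder = FALSE)[, 1]
  start <- t[first]; end <- t[last]
  dur <- end - start
  ns <- as.integer(rowsum(rep(1L, length(run)), rf, reorder = FALSE)[, 1])
  cx <- rowsum(w * x, rf, reorder = FALSE)[, 1] / sw
  cy <- rowsum(w * y, rf, reorder = FALSE)[, 1] / sw

  ok <- ns >= 2L & dur >= min_duration_ms
  data.frame(trial_id = tid[first][ok], start_ms = start[ok], end_ms = end[ok],
             duration_ms = dur[ok], centroid_x_px = unname(cx[ok]),
             centroid_y_px = unname(cy[ok]), n_samples = ns[ok],
             row.names = NULL, stringsAsFactors = FALSE)
}
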