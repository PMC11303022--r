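#' Read and write raw gaze logs
#'
#' The gaze log is a tab-separated file with header
#' `trial_id  t_ms  x_px  y_px  valid`, one eye-tracker sample per row,
#' samples within a trial strictly increasing in `t_ms` (negative times are
#' the pre-stimulus fixation window). `valid` is written as `0`/`1`.
#'
#' @param gaze data.frame with those five columns.
#' @param path File path.
#' @return `write_gaze_log()` returns `path` invisibly; `read_gaze_log()`
#'   returns the gaze data.frame.
#' @export
write_gaze_log <- function(gaze, path) {
  stopifnot(is.data.frame(gaze),
            all(c("trial_id", "t_ms", "x_px", "y_px", "valid") %in% names(gaze)))
  out <- gaze[, c("trial_id", "t_ms", "x_px", "y_px", "valid")]
  out$valid <- as.integer(out$valid)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gaze_log
#' @export
read_gaze_log <- function(path) {
  if (!file.exists(path)) stop_gb("gaze log not found: %s", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0) {
    warn_gb("empty gaze log: %s", path)
    return(data.frame(trial_id = character(0), t_ms = numeric(0),
                      x_px = numeric(0), y_px = numeric(0),
                      valid = logical(0), stringsAsFactors = FALSE))
  }
  gaze <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = "character",
                            stringsAsFactors = FALSE)
  need <- c("trial_id", "t_ms", "x_px", "y_px", "valid")
  if (!all(need %in% names(gaze))) {
    stop_gb("gaze log %s lacks columns: %s", path,
            paste(setdiff(need, names(gaze)), collapse = ", "))
  }
  for (cl in c("t_ms", "x_px", "y_px", "valid")) {
    gaze[[cl]] <- suppressWarnings(as.numeric(gaze[[cl]]))
  }
  bad <- which(!stats::complete.cases(gaze[, c("t_ms", "x_px", "y_px",
                                               "valid")]))
  if (length(bad)) {
    stop_gb("malformed gaze rows at line(s): %s",
            paste(utils::head(bad + 1L, 10), collapse = ", "))
  }
  # per-trial monotone timestamps (rows of one trial must be contiguous)
  dup <- unlist(tapply(gaze$t_ms, factor(gaze$trial_id, unique(gaze$trial_id)),
                       function(t) any(diff(t) <= 0)))
  if (any(dup)) {
    stop_gb("non-monotone t_ms within trial(s): %s",
            paste(names(dup)[dup], collapse = ", "))
  }
  gaze$valid <- gaze$valid != 0L
  gaze
}

#' Read and write trial manifests
#'
#' Comma-separated manifest with one row per trial: `trial_id, subject,
#' session, species_on_scene, emotion_category, emotional_side,
#' stimulus_pair_id`.
#'
#' @param manifest data.frame as produced by [simulate_gaze()].
#' @param path File path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_gb("manifest not found: %s", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "subject", "session", "species_on_scene",
            "emotion_category", "emotional_side")
  if (!all(need %in% names(man))) {
    stop_gb("manifest %s lacks columns: %s", path,
            paste(setdiff(need, names(man)), collapse = ", "))
  }
  bad_em <- setdiff(unique(man$emotion_category), emotion_levels())
  if (length(bad_em)) {
    stop_gb("unknown emotion_category: %s", paste(bad_em, collapse = ", "))
  }
  man
}

#' Write the ground-truth sidecar of a simulated dataset
#'
#' JSON record of every latent value of the generator (per-trial dwell
#' proportions, random intercepts, nuisance flags) alongside the config,
#' sufficient to recompute every generated dwell proportion.
#'
#' @param dataset A `"gaze_dataset"` from [simulate_gaze()].
#' @param path File path for the JSON sidecar.
#' @export
write_truth <- function(dataset, path) {
  stopifnot(inherits(dataset, "gaze_dataset"))
  cfg <- dataset$config
  cfg$bias_by_condition <- as.list(cfg$bias_by_condition)
  cfg$drift_px_by_session <- as.list(cfg$drift_px_by_session)
  jsonlite::write_json(list(config = unclass(cfg), truth = dataset$truth),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$truth
}

#' Save a full simulated dataset to a directory
#'
#' Writes `gaze.tsv`, `manifest.csv` and `truth.json` under `dir`.
#'
#' @param dataset A `"gaze_dataset"`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(gaze = file.path(dir, "gaze.tsv"),
             manifest = file.path(dir, "manifest.csv"),
             truth = file.path(dir, "truth.json"))
  if (!is.null(dataset$gaze)) write_gaze_log(dataset$gaze, paths[["gaze"]])
  write_manifest(dataset$manifest, paths[["manifest"]])
  write_truth(dataset, paths[["truth"]])
  invisible(paths)
}
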