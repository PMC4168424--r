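#' Write a trial to disk
#'
#' One CSV per trial (a `time` column in seconds plus the 20 canonical
#' channels, header row, `.` decimal, no index column) and a JSON sidecar
#' `<stem>.gt.json` holding the ground truth and trial metadata. The pair
#' round-trips losslessly through [read_recording()].
#'
#' @param recording A validated `gait_recording`.
#' @param ground_truth The matching `gait_ground_truth`.
#' @param path Path to the CSV file (the sidecar uses the same stem).
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, ground_truth, path) {
  validate_recording(recording)
  df <- data.frame(time = recording$t, recording$channels, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(
    format = "gaitmode-trial", version = 1L,
    sample_rate = recording$sample_rate,
    subject_id = recording$subject_id, trial_id = recording$trial_id,
    set_variant = recording$set_variant,
    mode_segments = ground_truth$mode_segments,
    events_measured = ground_truth$events_measured,
    events_contralateral = ground_truth$events_contralateral)
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".gt.json")

#' Read a trial from disk
#'
#' Reads a CSV written by [write_recording()] (or any file following the
#' same dialect) and its ground-truth sidecar. Channel columns may appear
#' in any order as long as the canonical names are present; all recording
#' and ground-truth invariants are re-checked on load.
#'
#' @param path Path to the trial CSV.
#' @return A list with elements `recording` and `ground_truth`.
#' @export
read_recording <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df))
    stop("trial file is missing the 'time' column: ", path, call. = FALSE)
  missing <- setdiff(gait_channels(), names(df))
  if (length(missing))
    stop("trial file is missing channel column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  sc <- .sidecar_path(path)
  if (!file.exists(sc))
    stop("ground-truth sidecar not found: ", sc, call. = FALSE)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  rec <- gait_recording(
    t = df$time,
    channels = as.matrix(df[, gait_channels(), drop = FALSE]),
    subject_id = meta$subject_id %||% "S1",
    trial_id = meta$trial_id %||% "T1",
    set_variant = meta$set_variant %||% "A")
  gt <- gait_ground_truth(
    mode_segments = meta$mode_segments,
    events_measured = meta$events_measured,
    events_contralateral = meta$events_contralateral,
    set_variant = meta$set_variant %||% "A")
  bad <- validate_ground_truth(gt, rec)
  if (length(bad))
    stop("invalid ground truth in ", sc, ":\n  ",
         paste(bad, collapse = "\n  "), call. = FALSE)
  list(recording = rec, ground_truth = gt)
}
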