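#' Construct a gait sensor recording
#'
#' A recording is a fixed-layout 20-channel time series sampled at 100 Hz:
#' 8 plantar-pressure channels (4 per insole, measured foot first) and 12
#' inertial channels (pitch, roll and two acceleration axes for the thigh,
#' shank and foot of the measured leg). Pressures are in arbitrary force
#' units normalized so a typical single-support stance sum is about 1;
#' angles are in degrees and accelerations in m/s^2.
#'
#' @param t Numeric vector of sample timestamps in seconds, strictly
#'   increasing and uniformly spaced at 10 ms.
#' @param channels Numeric matrix (or data frame) with one column per entry
#'   of [gait_channels()], in that order (columns are reordered by name if
#'   all canonical names are present).
#' @param subject_id,trial_id Identifiers carried as metadata.
#' @param set_variant `"A"` if the measured leg leads locomotion
#'   transitions in this trial, `"B"` if the unmeasured leg leads.
#' @return An object of class `gait_recording`.
#' @export
gait_recording <- function(t, channels, subject_id = "S1", trial_id = "T1",
                           set_variant = c("A", "B")) {
  set_variant <- match.arg(set_variant)
  channels <- as.matrix(channels)
  if (!is.null(colnames(channels)) &&
      setequal(colnames(channels), gait_channels())) {
    channels <- channels[, gait_channels(), drop = FALSE]
  } else if (ncol(channels) == N_CHANNELS) {
    colnames(channels) <- gait_channels()
  }
  rec <- structure(
    list(sample_rate = SAMPLE_RATE_HZ, t = as.numeric(t), channels = channels,
         subject_id = subject_id, trial_id = trial_id,
         set_variant = set_variant),
    class = "gait_recording")
  validate_recording(rec)
  rec
}

#' Validate recording invariants
#'
#' Checks the fixed channel layout, uniform 10 ms timestamps and
#' non-negativity of the pressure channels; stops on the first violation.
#'
#' @param rec A `gait_recording`.
#' @return The recording, invisibly.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "gait_recording"))
  ch <- rec$channels
  if (ncol(ch) != N_CHANNELS || !identical(colnames(ch), gait_channels()))
    stop("recording must have exactly the 20 canonical channels in order",
         call. = FALSE)
  if (nrow(ch) != length(rec$t))
    stop("channel rows and timestamps differ in length", call. = FALSE)
  if (length(rec$t) >= 2) {
    dt <- diff(rec$t)
    bad <- which(abs(dt - SAMPLE_PERIOD_S) > 1e-9)
    if (length(bad))
      stop(sprintf(
        "timestamps not uniform at 10 ms: first bad interval after sample %d (dt = %.6g s)",
        bad[1], dt[bad[1]]), call. = FALSE)
  }
  press <- ch[, 1:8, drop = FALSE]
  if (anyNA(ch) || any(!is.finite(ch)))
    stop("non-finite values in channel data", call. = FALSE)
  if (any(press < 0))
    stop("pressure channels must be non-negative", call. = FALSE)
  invisible(rec)
}

#' @export
print.gait_recording <- function(x, ...) {
  cat(sprintf(
    "<gait_recording> subject %s, trial %s, Set-%s\n  %d samples (%.2f s) x %d channels at %d Hz\n",
    x$subject_id, x$trial_id, x$set_variant, length(x$t),
    if (length(x$t)) diff(range(x$t)) + SAMPLE_PERIOD_S else 0,
    ncol(x$channels), x$sample_rate))
  invisible(x)
}

#' Construct ground-truth annotation for a recording
#'
#' @param mode_segments Data frame with columns `mode`, `start`, `end`
#'   (seconds): contiguous, non-overlapping locomotion-mode segments whose
#'   boundaries are already placed by the official boundary rules (the
#'   moment a foot leaves the ground for stand-to-X, the final swing-leg
#'   contact for X-to-stand, mid-swing of the leading leg otherwise).
#' @param events_measured,events_contralateral Lists with numeric fields
#'   `foot_contact` and `foot_off` (event times in seconds, strictly
#'   alternating per foot).
#' @param set_variant `"A"` or `"B"` (see [gait_recording()]).
#' @return An object of class `gait_ground_truth`.
#' @export
gait_ground_truth <- function(mode_segments, events_measured,
                              events_contralateral,
                              set_variant = c("A", "B")) {
  set_variant <- match.arg(set_variant)
  mode_segments <- as.data.frame(mode_segments)
  stopifnot(all(c("mode", "start", "end") %in% names(mode_segments)))
  mode_segments$mode <- as.character(mode_segments$mode)
  .assert_modes(mode_segments$mode)
  norm_ev <- function(e) list(foot_contact = sort(as.numeric(e$foot_contact)),
                              foot_off = sort(as.numeric(e$foot_off)))
  structure(
    list(mode_segments = mode_segments,
         events_measured = norm_ev(events_measured),
         events_contralateral = norm_ev(events_contralateral),
         set_variant = set_variant),
    class = "gait_ground_truth")
}

#' @export
print.gait_ground_truth <- function(x, ...) {
  cat(sprintf("<gait_ground_truth> Set-%s, %d mode segments: %s\n",
              x$set_variant, nrow(x$mode_segments),
              paste(x$mode_segments$mode, collapse = " > ")))
  invisible(x)
}

.check_alternation <- function(ev, foot) {
  times <- c(ev$foot_contact, ev$foot_off)
  kind <- rep(c("contact", "off"), c(length(ev$foot_contact), length(ev$foot_off)))
  o <- order(times)
  kind <- kind[o]
  out <- character(0)
  if (length(kind) >= 2) {
    same <- which(kind[-1] == kind[-length(kind)])
    for (i in same)
      out <- c(out, sprintf("%s foot: consecutive %s events with no intervening %s (events %d, %d)",
                            foot, kind[i], setdiff(c("contact", "off"), kind[i]), i, i + 1L))
  }
  out
}

#' Diagnose ground-truth consistency
#'
#' Returns a character vector of violations (empty when valid): segment
#' coverage of the recording span, contiguity, per-foot alternation of
#' contact and off events, and events falling inside the recording span.
#' Unlike [validate_recording()] this never raises; it is meant for
#' reporting on externally produced annotations.
#'
#' @param gt A `gait_ground_truth`.
#' @param recording The matching `gait_recording`.
#' @return Character vector of human-readable violations.
#' @export
validate_ground_truth <- function(gt, recording) {
  out <- character(0)
  seg <- gt$mode_segments
  t0 <- recording$t[1]
  t1 <- recording$t[length(recording$t)]
  if (nrow(seg) == 0) return("no mode segments")
  if (abs(seg$start[1] - t0) > 1e-6)
    out <- c(out, sprintf("segments start at %.3f s but recording starts at %.3f s",
                          seg$start[1], t0))
  if (seg$end[nrow(seg)] < t1 - 1e-6)
    out <- c(out, sprintf("segments end at %.3f s but recording ends at %.3f s (coverage gap)",
                          seg$end[nrow(seg)], t1))
  if (nrow(seg) >= 2) {
    gaps <- which(abs(seg$start[-1] - seg$end[-nrow(seg)]) > 1e-6)
    for (i in gaps)
      out <- c(out, sprintf("segments %d and %d are not contiguous", i, i + 1L))
    dup <- which(seg$mode[-1] == seg$mode[-nrow(seg)])
    for (i in dup)
      out <- c(out, sprintf("adjacent segments %d and %d share mode %s", i, i + 1L, seg$mode[i]))
  }
  if (any(seg$end <= seg$start))
    out <- c(out, "segment with non-positive duration")
  out <- c(out, .check_alternation(gt$events_measured, "measured"),
           .check_alternation(gt$events_contralateral, "contralateral"))
  all_ev <- c(gt$events_measured$foot_contact, gt$events_measured$foot_off,
              gt$events_contralateral$foot_contact, gt$events_contralateral$foot_off)
  n_out <- sum(all_ev < t0 - 1e-9 | all_ev > t1 + 1e-9)
  if (n_out)
    out <- c(out, sprintf("%d event(s) outside the recording span", n_out))
  out
}
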