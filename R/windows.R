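#' Sliding-window specification
#'
#' Windows are right-aligned (the decision timestamp is the last sample),
#' advance by one 10 ms sample, and default to 150 ms (15 samples). Sizes
#' of 100-200 ms are supported for sweeps.
#'
#' @param size_ms Window size in ms (multiple of 10).
#' @param increment_ms Window increment in ms (fixed sampling grid; must
#'   be 10).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(size_ms = 150, increment_ms = 10) {
  if (increment_ms != 10)
    stop("window increment is fixed at the 10 ms sample period", call. = FALSE)
  if (size_ms %% 10 != 0 || size_ms < 20)
    stop("size_ms must be a multiple of the 10 ms sample period (>= 20)",
         call. = FALSE)
  structure(list(size_ms = size_ms, increment_ms = increment_ms,
                 size = as.integer(size_ms / 10)),
            class = "window_spec")
}

#' Official mode boundaries of a trial
#'
#' Recomputes the instant separating each pair of contiguous locomotion
#' modes from the ground-truth events: for stand-to-X transitions the
#' moment either foot leaves the ground; for X-to-stand the moment the
#' swing leg contacts the ground before standing still; for all other
#' transitions the midpoint of the swing period of the leg that first left
#' the previous terrain (resolved from the trial's leading-leg metadata).
#'
#' @param gt A `gait_ground_truth`.
#' @return Data frame with columns `time`, `from`, `to`.
#' @export
mode_boundaries <- function(gt) {
  seg <- gt$mode_segments
  if (nrow(seg) < 2)
    return(data.frame(time = numeric(0), from = character(0), to = character(0)))
  ev_m <- gt$events_measured
  ev_c <- gt$events_contralateral
  all_off <- sort(c(ev_m$foot_off, ev_c$foot_off))
  tol <- 0.02
  out <- data.frame(time = numeric(nrow(seg) - 1L),
                    from = seg$mode[-nrow(seg)], to = seg$mode[-1],
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(seg) - 1L)) {
    b0 <- seg$end[i]
    from <- out$from[i]; to <- out$to[i]
    if (from == "S") {
      cand <- all_off[all_off >= b0 - tol]
      if (!length(cand))
        stop(sprintf("S>%s at ~%.2f s: no foot-off event found", to, b0),
             call. = FALSE)
      out$time[i] <- cand[1]
    } else if (to == "S") {
      all_on <- sort(c(ev_m$foot_contact, ev_c$foot_contact))
      cand <- all_on[all_on <= b0 + tol]
      if (!length(cand))
        stop(sprintf("%s>S at ~%.2f s: no foot-contact event found", from, b0),
             call. = FALSE)
      out$time[i] <- cand[length(cand)]
    } else {
      leg <- leading_leg(from, to, gt$set_variant)
      ev <- if (leg == "M") ev_m else ev_c
      # the swing bracketing the terrain change: last off at/before the
      # segment edge, paired with that foot's next contact
      k <- which(ev$foot_off <= b0 + tol)
      ok <- FALSE
      if (length(k)) {
        off <- ev$foot_off[k[length(k)]]
        nxt <- ev$foot_contact[ev$foot_contact > off]
        if (length(nxt) && nxt[1] >= b0 - tol) {
          out$time[i] <- (off + nxt[1]) / 2
          ok <- TRUE
        }
      }
      if (!ok)
        stop(sprintf("%s>%s at ~%.2f s: no swing of the leading (%s) leg brackets the terrain change",
                     from, to, b0, leg), call. = FALSE)
    }
  }
  out
}

.mode_at <- function(times, boundaries, first_mode) {
  if (!nrow(boundaries)) return(rep(first_mode, length(times)))
  modes <- c(first_mode, boundaries$to)
  # a center sample exactly on the boundary belongs to the latter mode
  # (the strict more-than-half rule)
  idx <- findInterval(times, boundaries$time - 1e-9) + 1L
  modes[idx]
}

#' Segment a trial into labeled analysis windows
#'
#' Emits one window per sample from index `size` onward. The ground-truth
#' mode label follows the more-than-half rule against the official mode
#' boundaries (a window is labeled with the former mode only if strictly
#' more than half of its samples precede the boundary; an exact split goes
#' to the latter mode), and the phase label follows
#' [label_window_phase()] applied to `phase_stream`.
#'
#' @param recording A `gait_recording`.
#' @param gt Matching `gait_ground_truth`.
#' @param spec A [window_spec()].
#' @param phase_stream Per-sample phase labels aligned to the recording
#'   (sensor-driven at inference time; ground-truth-driven for training).
#' @return Data frame with columns `end_idx`, `end_time`, `phase`, `mode`.
#' @export
slide_windows <- function(recording, gt, spec = window_spec(),
                          phase_stream) {
  n <- length(recording$t)
  size <- spec$size
  if (n < size)
    stop(sprintf("recording has %d samples, shorter than one %d-sample window",
                 n, size), call. = FALSE)
  stopifnot(length(phase_stream) == n)
  b <- mode_boundaries(gt)
  end_idx <- seq.int(size, n)
  # >half rule == mode at the center sample (index start + floor(size/2))
  center_idx <- end_idx - size + 1L + size %/% 2L
  mode <- .mode_at(recording$t[center_idx], b, gt$mode_segments$mode[1])
  phase <- .window_phases(as.character(phase_stream), size)
  data.frame(end_idx = end_idx, end_time = recording$t[end_idx],
             phase = phase, mode = mode, stringsAsFactors = FALSE)
}

#' Assemble a pooled, phase-grouped training set
#'
#' Pools labeled windows (and their feature vectors) across trials and
#' Set-A/Set-B variants, grouped by gait phase for the phase-specific
#' classifier bank. The variant filter supports training-data combination
#' experiments.
#'
#' @param trials List of trials (`list(recording, ground_truth)`).
#' @param include_variants Character subset of `c("A", "B")`.
#' @param spec A [window_spec()].
#' @param contact A [contact_config()] used to derive the training phase
#'   stream from ground-truth contact (exact events).
#' @return A list with `features` (matrix), `phase`, `mode`, `trial` and
#'   `spec`, of class `gait_training_set`.
#' @export
assemble_training_set <- function(trials, include_variants = c("A", "B"),
                                  spec = window_spec(),
                                  contact = contact_config()) {
  sel <- Filter(function(tr) tr$recording$set_variant %in% include_variants,
                trials)
  if (!length(sel)) stop("no trials match the requested variants", call. = FALSE)
  feats <- vector("list", length(sel))
  meta <- vector("list", length(sel))
  for (i in seq_along(sel)) {
    tr <- sel[[i]]
    pw <- prepare_trial(tr, spec = spec, contact = contact)
    feats[[i]] <- pw$features
    meta[[i]] <- data.frame(phase = pw$windows$phase, mode = pw$windows$mode,
                            trial = i, stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta)
  structure(list(features = do.call(rbind, feats), phase = meta$phase,
                 mode = meta$mode, trial = meta$trial, spec = spec),
            class = "gait_training_set")
}

# contact series reconstructed from ground-truth events on the sample grid
.contact_from_events <- function(ev, t) {
  on <- findInterval(t + 1e-12, sort(ev$foot_contact))
  off <- findInterval(t + 1e-12, sort(ev$foot_off))
  # in contact at t=0 iff first event is an off
  first_off <- length(ev$foot_off) &&
    (!length(ev$foot_contact) || min(ev$foot_off) < min(ev$foot_contact))
  if (first_off) on - off + 1L > 0L else on - off > 0L
}

#' Windows, phases and features for one trial
#'
#' Convenience wrapper running the first-level pipeline on a trial:
#' contact detection, phase segmentation, window labeling and feature
#' extraction. With `phase_source = "sensors"` the phase stream is derived
#' from the insole channels (as online); with `"events"` it is built from
#' the exact ground-truth events (training).
#'
#' @param trial `list(recording, ground_truth)`.
#' @param spec A [window_spec()].
#' @param contact A [contact_config()].
#' @param phase_source `"events"` or `"sensors"`.
#' @return List with `windows` (from [slide_windows()]), `features`
#'   (window x 120 matrix) and `phase_stream`.
#' @export
prepare_trial <- function(trial, spec = window_spec(),
                          contact = contact_config(),
                          phase_source = c("events", "sensors")) {
  phase_source <- match.arg(phase_source)
  rec <- trial$recording
  gt <- trial$ground_truth
  if (phase_source == "sensors") {
    cm <- detect_contact(rec$channels[, 1:4, drop = FALSE], contact, rec$t)
    cc <- detect_contact(rec$channels[, 5:8, drop = FALSE], contact, rec$t)
  } else {
    cm <- .contact_from_events(gt$events_measured, rec$t)
    cc <- .contact_from_events(gt$events_contralateral, rec$t)
  }
  ps <- segment_phases(cm, cc)
  win <- slide_windows(rec, gt, spec, ps)
  feats <- window_features(rec$channels, spec$size)
  list(windows = win, features = feats, phase_stream = as.character(ps))
}
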