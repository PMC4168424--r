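#' Segment the gait cycle into phases from both feet's contact state
#'
#' A four-state machine anchored on the measured leg: measured foot-contact
#' starts initial double stance (DS1), contralateral foot-off starts single
#' stance (SS), contralateral foot-contact starts terminal double stance
#' (DS2), and measured foot-off starts swing (SW). States persist between
#' triggering events, so standing (no new events) holds the current
#' double-stance state and every phase classifier sees standing windows.
#' Measured-leg events always dictate the state; a contralateral trigger
#' that is impossible given the measured foot's state (e.g. an SS trigger
#' while the measured foot is airborne) is logged and the state held.
#'
#' @param contact_measured,contact_contralateral Aligned logical contact
#'   series (from [detect_contact()] or built from ground-truth events).
#' @return A character vector of phase labels per sample, with attribute
#'   `anomalies` (indices of held impossible triggers).
#' @export
segment_phases <- function(contact_measured, contact_contralateral) {
  cm <- as.logical(contact_measured)
  cc <- as.logical(contact_contralateral)
  n <- length(cm)
  stopifnot(length(cc) == n)
  # initial state from the static contact pattern
  state <- if (cm[1] && cc[1]) "DS1" else if (cm[1] && !cc[1]) "SS"
           else "SW"
  phase <- character(n)
  anomalies <- integer(0)
  phase[1] <- state
  if (n >= 2) {
    dm <- diff(cm)
    dc <- diff(cc)
    ev_idx <- which(dm != 0L | dc != 0L) + 1L
    prev <- 1L
    for (i in ev_idx) {
      if (i > prev + 1L) phase[prev:(i - 1L)] <- state
      if (dm[i - 1L] == 1L) state <- "DS1"
      else if (dm[i - 1L] == -1L) state <- "SW"
      if (dc[i - 1L] == 1L) {
        if (cm[i]) state <- "DS2" else anomalies <- c(anomalies, i)
      } else if (dc[i - 1L] == -1L) {
        if (cm[i]) state <- "SS" else anomalies <- c(anomalies, i)
      }
      phase[i] <- state
      prev <- i
    }
    if (prev < n) phase[prev:n] <- state
  }
  structure(phase, anomalies = anomalies)
}

#' Label an analysis window with a gait phase
#'
#' Implements the majority rule for windows straddling phase boundaries:
#' a window spanning two adjacent phases is labeled with the former phase
#' only if strictly more than half of its samples precede the boundary
#' (an exact split goes to the latter phase); windows within one phase
#' keep that phase; windows spanning three or more phases take the phase
#' with the most samples (ties to the latest-occurring phase).
#'
#' @param phase_slice Character vector of per-sample phase labels covering
#'   the window (at least one sample).
#' @return A single phase label.
#' @export
label_window_phase <- function(phase_slice) {
  phase_slice <- as.character(phase_slice)
  if (!length(phase_slice)) stop("empty phase slice", call. = FALSE)
  cnt <- table(phase_slice)
  top <- names(cnt)[cnt == max(cnt)]
  if (length(top) == 1L) return(top)
  # tie: the phase whose samples occur latest in the window wins
  last_pos <- vapply(top, function(p) max(which(phase_slice == p)), 0L)
  top[which.max(last_pos)]
}

# vectorized window phase labels: counts per phase over sliding windows,
# tie-broken toward the phase occurring latest in the window
.window_phases <- function(phase, size) {
  n <- length(phase)
  n_win <- n - size + 1L
  idx <- seq_len(n)
  score <- matrix(0, n_win, 4L)
  phases <- gait_phases()
  for (p in seq_along(phases)) {
    ind <- as.integer(phase == phases[p])
    cs <- cumsum(ind)
    cnt <- cs[seq(size, n)] - c(0, cs[seq_len(n - size)])
    lastpos <- cummax(ifelse(ind == 1L, idx, 0L))[seq(size, n)]
    score[, p] <- cnt * (n + 1) + lastpos
  }
  phases[max.col(score, ties.method = "first")]
}
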