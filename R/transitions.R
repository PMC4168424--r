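# event-driven phase machine over ground-truth event times; returns the
# times at which each phase is entered
.phase_entries <- function(gt) {
  ev <- rbind(
    data.frame(time = gt$events_measured$foot_contact, leg = "M", kind = "on"),
    data.frame(time = gt$events_measured$foot_off, leg = "M", kind = "off"),
    data.frame(time = gt$events_contralateral$foot_contact, leg = "C", kind = "on"),
    data.frame(time = gt$events_contralateral$foot_off, leg = "C", kind = "off"))
  ev <- ev[order(ev$time), , drop = FALSE]
  cm <- TRUE  # both feet loaded at trial start
  state <- "DS1"
  out <- data.frame(time = 0, phase = "DS1", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ev))) {
    new <- state
    if (ev$leg[i] == "M") {
      cm <- ev$kind[i] == "on"
      new <- if (cm) "DS1" else "SW"
    } else {
      if (cm) new <- if (ev$kind[i] == "on") "DS2" else "SS"
    }
    if (new != state) {
      out <- rbind(out, data.frame(time = ev$time[i], phase = new))
      state <- new
    }
  }
  out
}

#' Transition and steady periods of a trial
#'
#' Splits the trial around each mode change: stand-to-X periods run from
#' the moment either foot leaves the ground to the beginning of the next
#' single-stance phase; X-to-stand periods last exactly the final swing
#' (swing-leg foot-off to its contact before standing still); all other
#' transition periods run from the leading leg's foot-off just before the
#' terrain change to the beginning of the first single-stance phase after
#' the official boundary. The complement of the transition periods is the
#' steady locomotion period.
#'
#' @param gt A `gait_ground_truth`.
#' @return Data frame of transition events with columns `from`, `to`,
#'   `start`, `end`, `boundary`.
#' @export
transition_periods <- function(gt) {
  b <- mode_boundaries(gt)
  if (!nrow(b)) return(data.frame(from = character(0), to = character(0),
                                  start = numeric(0), end = numeric(0),
                                  boundary = numeric(0)))
  pe <- .phase_entries(gt)
  ss_onsets <- pe$time[pe$phase == "SS"]
  all_off <- sort(c(gt$events_measured$foot_off, gt$events_contralateral$foot_off))
  out <- data.frame(from = b$from, to = b$to, start = NA_real_, end = NA_real_,
                    boundary = b$time, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(b))) {
    if (b$from[i] == "S") {
      out$start[i] <- b$time[i]  # boundary is the first foot-off
      nxt <- ss_onsets[ss_onsets > b$time[i] + 1e-9]
      if (!length(nxt)) stop("no SS phase after S>", b$to[i], call. = FALSE)
      out$end[i] <- nxt[1]
    } else if (b$to[i] == "S") {
      # the final swing: last foot-off before the closing contact
      off <- all_off[all_off < b$time[i] - 1e-9]
      if (!length(off)) stop("no swing before ", b$from[i], ">S", call. = FALSE)
      out$start[i] <- off[length(off)]
      out$end[i] <- b$time[i]
    } else {
      leg <- leading_leg(b$from[i], b$to[i], gt$set_variant)
      ev <- if (leg == "M") gt$events_measured else gt$events_contralateral
      off <- ev$foot_off[ev$foot_off < b$time[i]]
      if (!length(off))
        stop("no leading-leg foot-off before ", b$from[i], ">", b$to[i],
             call. = FALSE)
      out$start[i] <- off[length(off)]
      nxt <- ss_onsets[ss_onsets > b$time[i] + 1e-9]
      if (!length(nxt))
        stop("no SS phase after ", b$from[i], ">", b$to[i], call. = FALSE)
      out$end[i] <- nxt[1]
    }
  }
  out
}

#' Attach critical moments to transition events
#'
#' The critical moment is the deadline against which prediction time is
#' scored: for X-to-stand transitions, the moment the swing leg contacts
#' the ground before standing still (the period end); for all other
#' transitions, the measured foot's first contact (DS1 onset) in the
#' period.
#'
#' @param events Data frame from [transition_periods()].
#' @param gt The matching `gait_ground_truth`.
#' @return `events` with an additional column `t_c`.
#' @export
critical_moments <- function(events, gt) {
  events$t_c <- NA_real_
  fc <- sort(gt$events_measured$foot_contact)
  for (i in seq_len(nrow(events))) {
    if (events$to[i] == "S") {
      events$t_c[i] <- events$end[i]
    } else {
      cand <- fc[fc >= events$start[i] - 1e-9 & fc <= events$end[i] + 0.02]
      if (!length(cand))
        stop("no measured foot-contact in transition period ",
             events$from[i], ">", events$to[i], call. = FALSE)
      events$t_c[i] <- cand[1]
    }
  }
  events
}

#' Score the detection of one locomotion transition
#'
#' A transition is detected when a run of at least `min_run` consecutive
#' decisions equal to the new mode starts within the transition period
#' (the run may complete beyond the period end) and no decision after the
#' run's start and within the period differs from the new mode. The
#' prediction time is `t_c - t_pre`, where `t_pre` is the time of the
#' run's first decision; negative values mean the detection came after
#' the critical moment.
#'
#' @param decisions A `gaitlda_stream` (or data frame with `time` and `D`).
#' @param event One row of [critical_moments()] output.
#' @param min_run Minimum run length ("more than 30 consecutive correct
#'   decisions" = 31 at the 10 ms decision rate).
#' @return A list with `detected`, `t_pre` and `T_pre` (seconds).
#' @export
detect_transition <- function(decisions, event, min_run = 31L) {
  in_per <- which(decisions$time >= event$start - 1e-9 &
                    decisions$time <= event$end + 1e-9)
  if (!length(in_per))
    return(list(detected = FALSE, t_pre = NA_real_, T_pre = NA_real_))
  to <- event$to
  D <- decisions$D
  wrong <- in_per[D[in_per] != to]
  first_ok <- if (length(wrong)) {
    after <- in_per[in_per > wrong[length(wrong)]]
    after[D[after] == to][1]
  } else in_per[D[in_per] == to][1]
  if (is.na(first_ok) || !length(first_ok))
    return(list(detected = FALSE, t_pre = NA_real_, T_pre = NA_real_))
  # run may continue beyond the period end
  run_end <- first_ok
  while (run_end < length(D) && D[run_end + 1L] == to) run_end <- run_end + 1L
  if (run_end - first_ok + 1L < min_run)
    return(list(detected = FALSE, t_pre = NA_real_, T_pre = NA_real_))
  t_pre <- decisions$time[first_ok]
  list(detected = TRUE, t_pre = t_pre, T_pre = event$t_c - t_pre)
}

#' Adjusted prediction time of a trial
#'
#' `APD = sum_i T_pre_i - T_max * N_miss`: the summed prediction times of
#' the detected transitions minus a fixed penalty per missed detection.
#'
#' @param outcomes Data frame (or list of lists) with columns `detected`
#'   and `T_pre` (seconds), one row per transition of the trial.
#' @param T_max Miss penalty in seconds (default 2 s).
#' @return List with `APD` (seconds), `n`, `n_miss` and `sum_T_pre`.
#' @export
adjusted_prediction_time <- function(outcomes, T_max = 2) {
  if (!is.data.frame(outcomes))
    outcomes <- do.call(rbind, lapply(outcomes, as.data.frame))
  det <- outcomes$detected
  s <- sum(outcomes$T_pre[det])
  n_miss <- sum(!det)
  list(APD = s - T_max * n_miss, n = nrow(outcomes), n_miss = n_miss,
       sum_T_pre = s)
}
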