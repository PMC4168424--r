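#' Foot-contact detector configuration
#'
#' Contact is detected by hysteresis thresholding of the 4-sensor insole
#' sum: the foot enters contact when the (lightly smoothed) sum rises
#' above `theta_on` and leaves contact when it falls below `theta_off`.
#' The defaults are 30% and 15% of the nominal single-support stance sum,
#' which is about 1 in this package's normalized pressure units; fixed
#' thresholds keep the detector strictly causal (no whole-trial
#' calibration pass). A refractory debounce ignores any state change
#' within `min_state_ms` of the previous one, so genuine events are timed
#' without delay while threshold chatter is suppressed.
#'
#' @param theta_on,theta_off Contact thresholds in pressure units
#'   (`theta_on > theta_off > 0`).
#' @param min_state_ms Debounce (refractory) duration in ms.
#' @return An object of class `contact_config`.
#' @export
contact_config <- function(theta_on = 0.30, theta_off = 0.15,
                           min_state_ms = 50) {
  if (!(theta_on > theta_off && theta_off > 0))
    stop("need theta_on > theta_off > 0", call. = FALSE)
  structure(list(theta_on = theta_on, theta_off = theta_off,
                 min_state_ms = min_state_ms),
            class = "contact_config")
}

#' Detect foot contact from insole pressure
#'
#' @param insole Numeric matrix with the four pressure channels of one
#'   insole (non-negative), one row per sample.
#' @param config A [contact_config()].
#' @param t Optional timestamps (s); defaults to 10 ms spacing from 0.
#' @return A logical contact vector with attributes `foot_contact` and
#'   `foot_off` (event times in seconds, the first sample at which the new
#'   state holds) and `thresholds`.
#' @export
detect_contact <- function(insole, config = contact_config(), t = NULL) {
  insole <- as.matrix(insole)
  if (any(insole < 0)) stop("insole pressures must be non-negative", call. = FALSE)
  n <- nrow(insole)
  if (is.null(t)) t <- (seq_len(n) - 1L) * SAMPLE_PERIOD_S
  s_raw <- rowSums(insole)
  # short causal smoothing so rectified swing noise cannot reach theta_on
  s <- 0.6 * s_raw + 0.4 * c(s_raw[1], s_raw[-n])
  th_on <- config$theta_on
  th_off <- config$theta_off
  refr <- max(1L, round(config$min_state_ms / 1000 / SAMPLE_PERIOD_S))
  contact <- logical(n)
  # initial state from the first few samples (robust to single-sample noise)
  state <- mean(s[seq_len(min(5L, n))]) > (th_on + th_off) / 2
  last_change <- -refr - 1L
  for (i in seq_len(n)) {
    if (!state && s[i] > th_on && i - last_change > refr) {
      state <- TRUE; last_change <- i
    } else if (state && s[i] < th_off && i - last_change > refr) {
      state <- FALSE; last_change <- i
    }
    contact[i] <- state
  }
  d <- diff(contact)
  structure(contact,
            foot_contact = t[which(d == 1L) + 1L],
            foot_off = t[which(d == -1L) + 1L],
            thresholds = c(on = th_on, off = th_off))
}

#' Extract contact/off event times from a contact series
#'
#' @param contact Logical vector from [detect_contact()].
#' @return A list with `foot_contact` and `foot_off` times.
#' @export
contact_events <- function(contact) {
  list(foot_contact = attr(contact, "foot_contact"),
       foot_off = attr(contact, "foot_off"))
}
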