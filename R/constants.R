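#' Canonical mode, phase and channel vocabularies
#'
#' `gait_modes()` returns the six locomotion modes in canonical order
#' (standing, level walking, stair ascent, stair descent, ramp ascent, ramp
#' descent); ties in classifier decisions are broken in this order.
#' `gait_phases()` returns the four adjacent gait phases (initial double
#' stance, single stance, terminal double stance, swing).
#' `gait_channels()` returns the fixed 20-channel layout of a recording:
#' four pressure channels per insole (big toe, 1st metatarsal, 4th
#' metatarsal, heel; measured then contralateral foot) followed by pitch,
#' roll and two acceleration axes for the thigh, shank and foot of the
#' measured leg.
#'
#' @return A character vector.
#' @export
gait_modes <- function() c("S", "W", "SA", "SD", "RA", "RD")

#' @rdname gait_modes
#' @export
gait_phases <- function() c("DS1", "SS", "DS2", "SW")

#' @rdname gait_modes
#' @export
gait_channels <- function() {
  c(paste0("insoleM_p", 1:4), paste0("insoleC_p", 1:4),
    paste0(rep(c("thigh", "shank", "foot"), each = 4L),
           "_", c("pitch", "roll", "ax", "ay")))
}

# sampling setup is fixed across the package: 100 Hz, 10 ms period
SAMPLE_RATE_HZ <- 100
SAMPLE_PERIOD_S <- 0.01

N_CHANNELS <- 20L

FEATURE_NAMES <- c("max", "min", "mean", "wl", "std", "rms")

.assert_modes <- function(x, arg = "mode") {
  bad <- setdiff(unique(as.character(x)), gait_modes())
  if (length(bad))
    stop(sprintf("unknown %s label(s): %s", arg, paste(bad, collapse = ", ")),
         call. = FALSE)
  invisible(x)
}

.assert_phases <- function(x) {
  bad <- setdiff(unique(as.character(x)), gait_phases())
  if (length(bad))
    stop("unknown phase label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  invisible(x)
}
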