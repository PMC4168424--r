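.TEN_TRANSITIONS <- c("S>W", "W>SA", "SA>W", "W>RD", "RD>W",
                      "W>S", "W>RA", "RA>W", "W>SD", "SD>W")

# transitions for which the measured leg is the leading leg in Set-A trials
.MEASURED_LEADS_A <- c("S>W", "W>SA", "SA>W", "W>RD", "RD>W", "W>RA")

#' Which leg leads a locomotion transition
#'
#' In Set-A trials the measured (instrumented) leg takes the first step onto
#' the new terrain for S>W, W>SA, SA>W, W>RD, RD>W and W>RA; the unmeasured
#' leg leads the remaining four transition types. Set-B mirrors this
#' assignment. For X>S transitions the "leading" leg is the one whose final
#' swing ends the locomotion bout.
#'
#' @param from,to Mode labels of the transition.
#' @param set_variant `"A"` or `"B"`.
#' @return `"M"` (measured) or `"C"` (contralateral).
#' @export
leading_leg <- function(from, to, set_variant = c("A", "B")) {
  set_variant <- match.arg(set_variant)
  key <- paste0(from, ">", to)
  if (!key %in% .TEN_TRANSITIONS)
    stop("no leading-leg rule for transition ", key, call. = FALSE)
  m_leads <- key %in% .MEASURED_LEADS_A
  if (set_variant == "B") m_leads <- !m_leads
  if (m_leads) "M" else "C"
}

#' Default experiment protocol
#'
#' The task sequence of one experiment trial: stand, walk, stair ascent,
#' walk, ramp descent, walk, stand/turn/stand, walk, ramp ascent, walk,
#' stair descent, walk, stand/turn/stand. Turn-back bouts are dynamic
#' standing (small alternating steps, mode S) flanked by static standing,
#' and belong to the same standing segment as the flanking stands. The
#' sequence contains each of the ten transition types at least once, with
#' S>W and W>S occurring twice. Set-B uses the same mode sequence; only the
#' leading-leg metadata differs.
#'
#' @param set_variant `"A"` or `"B"`.
#' @param steps_per_bout Steps (single-leg swings) per level-walking bout;
#'   stair/ramp bouts use two fewer (at least 2). The generator may add one
#'   step to a bout so that the required leg leads the next transition.
#' @param stand_duration Duration (s) of the opening static stand.
#' @param turn_stand Duration (s) of each static stand flanking a turn.
#' @return A data frame with columns `mode`, `kind` (`"stand"`, `"gait"`,
#'   `"turn"`), `steps` and `duration` (s; `NA` for gait rows, whose length
#'   follows from the step count).
#' @export
default_protocol <- function(set_variant = c("A", "B"), steps_per_bout = 6L,
                             stand_duration = 2, turn_stand = 1) {
  set_variant <- match.arg(set_variant)
  g <- function(mode) data.frame(
    mode = mode, kind = "gait",
    steps = if (mode == "W") as.integer(steps_per_bout)
            else max(2L, as.integer(steps_per_bout) - 2L),
    duration = NA_real_, stringsAsFactors = FALSE)
  s <- function(kind, dur) data.frame(mode = "S", kind = kind,
                                      steps = if (kind == "turn") as.integer(steps_per_bout) else NA_integer_,
                                      duration = dur, stringsAsFactors = FALSE)
  out <- rbind(
    s("stand", stand_duration),
    g("W"), g("SA"), g("W"), g("RD"), g("W"),
    s("turn", turn_stand),
    g("W"), g("RA"), g("W"), g("SD"), g("W"),
    s("turn", turn_stand))
  attr(out, "set_variant") <- set_variant
  out
}
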