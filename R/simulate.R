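#' Simulator configuration
#'
#' Parameters of the synthetic gait generator. Defaults describe an
#' able-bodied protocol trial of roughly 40 s: 1.1 s gait cycles split into
#' the four phases as 12/38/12/38% of the cycle, per-channel Gaussian
#' sensor noise of 0.05 template units, and unit inter-mode template
#' separation.
#'
#' @param seed Integer seed; identical configurations produce bit-identical
#'   trials.
#' @param cycle_duration Gait cycle period in seconds.
#' @param phase_fractions Fractions of the cycle spent in DS1, SS, DS2 and
#'   SW; must be positive and sum to 1.
#' @param noise_sd Additive Gaussian noise sigma per channel, in template
#'   units (each channel's physical scale multiplies both template and
#'   noise, so this is a fraction of the channel's characteristic range).
#' @param mode_separation Non-negative scalar multiplying all inter-mode
#'   template offsets; 0 collapses the modes onto the level-walking
#'   template.
#' @param steps_per_bout Steps per level-walking bout (see
#'   [default_protocol()]).
#' @param set_variant `"A"` (measured leg leads transitions) or `"B"`.
#' @param stand_duration,turn_stand Static standing durations (s).
#' @param turn_amplitude Relative movement amplitude of dynamic-standing
#'   (turn-back) steps.
#' @param subject_sd,subject_mode_sd,trial_mode_sd Standard deviations of
#'   the per-subject channel offsets, per-subject per-mode template
#'   jitter, and per-trial per-mode template jitter (template units).
#' @param artifact_rate Rate (per second) of brief motion artifacts on the
#'   inertial channels of one sensor module.
#' @param artifact_amp Artifact offset amplitude in template units; scales
#'   with the noise level by default, so noiseless simulation is fully
#'   deterministic.
#' @param artifact_ms Artifact duration range in ms.
#' @param wander_sd Stationary standard deviation (template units) of the
#'   stride-to-stride baseline wander on the inertial channels, modeling
#'   movement-execution variability; scales with the noise level by
#'   default.
#' @param wander_tau Correlation time (s) of the baseline wander.
#' @param spike_rate Rate (per second per inertial channel) of
#'   single-sample spike outliers.
#' @param spike_amp Spike amplitude scale in template units; scales with
#'   the noise level by default.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, cycle_duration = 1.1,
                       phase_fractions = c(DS1 = 0.12, SS = 0.38, DS2 = 0.12, SW = 0.38),
                       noise_sd = 0.05, mode_separation = 1,
                       steps_per_bout = 6L, set_variant = c("A", "B"),
                       stand_duration = 2, turn_stand = 1,
                       turn_amplitude = 0.25,
                       subject_sd = 0.08, subject_mode_sd = 0.008,
                       trial_mode_sd = 0.007,
                       artifact_rate = 0.12, artifact_amp = 3 * noise_sd,
                       artifact_ms = c(40, 70),
                       wander_sd = 0.2 * noise_sd, wander_tau = 0.04,
                       spike_rate = 0, spike_amp = 8 * noise_sd) {
  set_variant <- match.arg(set_variant)
  phase_fractions <- as.numeric(phase_fractions)
  if (length(phase_fractions) != 4 || any(phase_fractions <= 0))
    stop("phase_fractions must be four positive numbers", call. = FALSE)
  if (abs(sum(phase_fractions) - 1) > 1e-9)
    stop("phase_fractions must sum to 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (mode_separation < 0) stop("mode_separation must be >= 0", call. = FALSE)
  if (steps_per_bout < 2) stop("steps_per_bout must be >= 2", call. = FALSE)
  structure(list(
    seed = as.integer(seed), cycle_duration = cycle_duration,
    phase_fractions = stats::setNames(phase_fractions, gait_phases()),
    noise_sd = noise_sd, mode_separation = mode_separation,
    steps_per_bout = as.integer(steps_per_bout), set_variant = set_variant,
    stand_duration = stand_duration, turn_stand = turn_stand,
    turn_amplitude = turn_amplitude, subject_sd = subject_sd,
    subject_mode_sd = subject_mode_sd, trial_mode_sd = trial_mode_sd,
    artifact_rate = artifact_rate, artifact_amp = artifact_amp,
    artifact_ms = artifact_ms, wander_sd = wander_sd,
    wander_tau = wander_tau, spike_rate = spike_rate,
    spike_amp = spike_amp),
    class = "sim_config")
}

# ---- template constants ----------------------------------------------------

# IMU channel order: thigh/shank/foot x (pitch, roll, ax, ay)
.IMU_SCALE <- c(25, 8, 5, 5, 25, 8, 5, 5, 25, 8, 5, 5)
.IMU_AMP   <- c(0.80, 0.02, 0.45, 0.35, 1.00, 0.02, 0.50, 0.40, 1.10, 0.02, 0.55, 0.45)
.IMU_FREQ  <- c(1, 1, 2, 2, 1, 1, 2, 2, 1, 1, 2, 2)
.IMU_PHI   <- c(0, 0.7, 0.3, 1.1, -1.0, -0.3, 0.9, 1.7, -1.9, -1.2, 1.5, 2.3)

# inter-mode IMU template offsets (template units, multiplied by
# mode_separation); stair and ramp siblings are deliberately close so the
# classifier's residual confusion concentrates in SA/RA and SD/RD
.MODE_DELTA <- rbind(
  S  = rep(0, 12),
  W  = rep(0, 12),
  SA = c(0.90, 0.10, 0.40, 0.25, 0.70, 0.08, 0.30, 0.20, 0.50, 0.05, 0.25, 0.15),
  SD = c(-0.80, -0.08, -0.35, -0.22, -0.60, -0.07, -0.28, -0.18, -0.45, -0.04, -0.22, -0.14),
  RA = c(0.8766, 0.0563, 0.3896, 0.2435, 0.6818, 0.0363, 0.2922, 0.1948, 0.487, 0.0136, 0.2435, 0.1461),
  RD = c(-0.7792, -0.0363, -0.3409, -0.2143, -0.5844, -0.0263, -0.2727, -0.1753, -0.4383, -0.0036, -0.2143, -0.1364))

# insole channel amplitudes (p1 big toe, p2 1st met, p3 4th met, p4 heel)
.PRESS_AMP <- c(0.45, 0.60, 0.50, 0.85)
# per-mode loading factors: ascent loads the forefoot, descent the heel
.PRESS_FAC <- rbind(
  S  = c(0.55, 0.50, 0.50, 0.60),
  W  = c(1.00, 1.00, 1.00, 1.00),
  SA = c(1.40, 1.30, 1.05, 0.70),
  SD = c(0.66, 0.80, 1.06, 1.32),
  RA = c(1.36, 1.27, 1.04, 0.72),
  RD = c(0.69, 0.825, 1.055, 1.285))
.PRESS_STAND <- c(0.12, 0.13, 0.11, 0.14)  # per-channel level while standing

# per-mode cyclic amplitude factors: stair gait is more exaggerated than
# the ramp siblings, so amplitude-vs-offset shape must be integrated over
# the analysis window to separate the pairs
.MODE_AMPFAC <- c(S = 1, W = 1, SA = 1.08, SD = 1.05, RA = 1.08, RD = 1.05)

# confusable sibling of each mode (stair/ramp pairs)
.MODE_SIBLING <- c(S = NA, W = NA, SA = "RA", RA = "SA", SD = "RD", RD = "SD")
.ENTRY_EMPH <- 0.55

# template target for the first stride onto new terrain: stair/ramp
# entries are pushed away from their sibling mode along the fixed
# template direction (so the push survives per-trial template jitter);
# walking and standing entries keep the plain template
.entry_afac <- function(new) {
  sib <- .MODE_SIBLING[[new]]
  if (is.na(sib)) return(.MODE_AMPFAC[[new]])
  .MODE_AMPFAC[[new]] + .ENTRY_EMPH * (.MODE_AMPFAC[[new]] - .MODE_AMPFAC[[sib]])
}

.entry_push <- function(new, sep) {
  sib <- .MODE_SIBLING[[new]]
  if (is.na(sib)) return(rep(0, 12))
  .ENTRY_EMPH * sep * (.MODE_DELTA[new, ] - .MODE_DELTA[sib, ])
}

.sstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

.rcbump <- function(v, center, width) {
  ifelse(abs(v - center) < width / 2,
         0.5 * (1 + cos(2 * pi * (v - center) / width)), 0)
}

# Pressure of one stance over normalized stance time v in [0, 1], given the
# four (possibly mode-scaled) channel amplitudes. Loading and unloading
# edges are steep (a fraction of one 10 ms sample at normal stance
# durations) so detected contact events land within one sample of ground
# truth, and toe-off ends on a mode-independent push-off plateau so the
# pre-off pressure level is uniform across modes.
.stance_pressure <- function(v, amps) {
  edge <- .sstep(v / 0.002) * .sstep((1 - v) / 0.0147)
  heel <- ifelse(v < 0.28, 1,
                 ifelse(v < 0.58, 0.5 * (1 + cos(pi * (v - 0.28) / 0.30)), 0))
  met4 <- .rcbump(v, 0.42, 0.50)
  met1 <- .rcbump(v, 0.60, 0.50)
  toe  <- .rcbump(v, 0.68, 0.30)
  p <- cbind(toe * amps[1], met1 * amps[2], met4 * amps[3], heel * amps[4])
  p[, 1] <- p[, 1] + 0.40 * .sstep((v - 0.70) / 0.10)
  p * edge
}

# ---- subject templates -----------------------------------------------------

#' Draw a synthetic subject template perturbation
#'
#' Each synthetic subject perturbs the shared signal templates with fixed
#' per-channel offsets, a movement amplitude factor, per-mode template
#' jitter and insole gain factors. The perturbation is fixed across all of
#' the subject's trials.
#'
#' @param seed Integer seed.
#' @param config A [sim_config()].
#' @return A list of perturbation draws (class `gait_subject`).
#' @export
make_subject <- function(seed, config = sim_config()) {
  with_local_seed(seed, {
    structure(list(
      seed = as.integer(seed),
      off = stats::rnorm(12, 0, config$subject_sd),
      ampfac = max(0.5, stats::rnorm(1, 1, 0.05)),
      mode_jitter = matrix(stats::rnorm(72, 0, config$subject_mode_sd), 6, 12,
                           dimnames = list(rownames(.MODE_DELTA), NULL)),
      press_fac = pmax(0.7, stats::rnorm(4, 1, 0.04))),
      class = "gait_subject")
  })
}

.neutral_subject <- function() {
  structure(list(seed = NA_integer_, off = rep(0, 12), ampfac = 1,
                 mode_jitter = matrix(0, 6, 12, dimnames = list(rownames(.MODE_DELTA), NULL)),
                 press_fac = rep(1, 4)),
            class = "gait_subject")
}

# ---- timeline construction -------------------------------------------------

# Lay the protocol out as an event timeline: one row per step (single-leg
# swing) with leg, foot-off/foot-contact times, landing mode and stretch id,
# plus official mode boundaries and stretch spans.
.build_timeline <- function(protocol, config) {
  Tc <- config$cycle_duration
  fr <- config$phase_fractions
  swing_M <- fr[["SW"]] * Tc
  swing_C <- fr[["SS"]] * Tc
  ds_after_M <- fr[["DS1"]] * Tc  # delay from measured landing to contra off
  ds_after_C <- fr[["DS2"]] * Tc
  variant <- attr(protocol, "set_variant") %||% config$set_variant

  steps <- list()
  stretches <- list()
  boundaries <- list()
  cursor <- 0
  i <- 1L
  n_rows <- nrow(protocol)
  while (i <= n_rows) {
    row <- protocol[i, ]
    if (row$kind == "stand") {
      cursor <- cursor + row$duration
      i <- i + 1L
    } else if (row$kind == "turn") {
      cursor <- cursor + row$duration
      st <- .lay_stretch(cursor, "S", row$steps,
                         lead = if (variant == "A") "M" else "C",
                         final_leg = NULL, variant = variant,
                         swing_M, swing_C, ds_after_M, ds_after_C)
      steps[[length(steps) + 1L]] <- st$steps
      stretches[[length(stretches) + 1L]] <-
        data.frame(start = cursor, end = st$t_end, amp = config$turn_amplitude)
      cursor <- st$t_end + row$duration
      i <- i + 1L
    } else {
      j <- i
      while (j < n_rows && protocol$kind[j + 1L] == "gait") j <- j + 1L
      modes <- protocol$mode[i:j]
      if (any(modes[-1] == modes[-length(modes)]))
        stop("protocol contains adjacent identical modes; no boundary is definable",
             call. = FALSE)
      st <- .lay_stretch(cursor, modes, protocol$steps[i:j],
                         lead = vapply(seq_along(modes), function(b)
                           leading_leg(if (b == 1) "S" else modes[b - 1L], modes[b], variant),
                           character(1)),
                         final_leg = leading_leg(modes[length(modes)], "S", variant),
                         variant = variant,
                         swing_M, swing_C, ds_after_M, ds_after_C)
      steps[[length(steps) + 1L]] <- st$steps
      stretches[[length(stretches) + 1L]] <-
        data.frame(start = cursor, end = st$t_end, amp = 1)
      boundaries[[length(boundaries) + 1L]] <- st$boundaries
      cursor <- st$t_end
      i <- j + 1L
    }
  }
  list(steps = do.call(rbind, steps),
       stretches = do.call(rbind, stretches),
       boundaries = do.call(rbind, boundaries),
       duration = cursor)
}

# one continuous locomotion stretch (no intervening stand)
.lay_stretch <- function(t_start, modes, nominal_steps, lead, final_leg, variant,
                         swing_M, swing_C, ds_after_M, ds_after_C) {
  B <- length(modes)
  n_steps <- as.integer(nominal_steps)
  if (length(lead) == 1L) lead <- rep(lead, B)
  # parity fixes: the first step of each bout must be taken by its leading
  # leg, and the final landing by the leg that leads the X>S transition
  leg_cur <- lead[1]
  for (b in seq_len(B)) {
    if (b < B) {
      end_leg <- if (n_steps[b] %% 2L == 0L) leg_cur else setdiff(c("M", "C"), leg_cur)
      if (end_leg != lead[b + 1L]) n_steps[b] <- n_steps[b] + 1L
      leg_cur <- lead[b + 1L]
    } else if (!is.null(final_leg)) {
      last_leg <- if (n_steps[b] %% 2L == 1L) leg_cur else setdiff(c("M", "C"), leg_cur)
      if (last_leg != final_leg) n_steps[b] <- n_steps[b] + 1L
    }
  }
  total <- sum(n_steps)
  leg <- character(total); t_off <- t_on <- numeric(total)
  mode <- rep(modes, n_steps)
  bout <- rep(seq_len(B), n_steps)
  cur_leg <- lead[1]
  cur_off <- t_start
  for (k in seq_len(total)) {
    leg[k] <- cur_leg
    t_off[k] <- cur_off
    dur <- if (cur_leg == "M") swing_M else swing_C
    t_on[k] <- cur_off + dur
    cur_off <- t_on[k] + if (cur_leg == "M") ds_after_M else ds_after_C
    cur_leg <- setdiff(c("M", "C"), cur_leg)
  }
  boundaries <- NULL
  if (B >= 1 && modes[1] != "S") {
    b_times <- numeric(0); b_from <- b_to <- character(0)
    b_times <- t_start; b_from <- "S"; b_to <- modes[1]
    if (B >= 2) for (b in 2:B) {
      k <- which(bout == b)[1]
      b_times <- c(b_times, t_off[k] + (t_on[k] - t_off[k]) / 2)
      b_from <- c(b_from, modes[b - 1L]); b_to <- c(b_to, modes[b])
    }
    b_times <- c(b_times, t_on[total])
    b_from <- c(b_from, modes[B]); b_to <- c(b_to, "S")
    boundaries <- data.frame(time = b_times, from = b_from, to = b_to,
                             stringsAsFactors = FALSE)
  }
  list(steps = data.frame(leg = leg, t_off = t_off, t_on = t_on, mode = mode,
                          stringsAsFactors = FALSE),
       t_end = t_on[total], boundaries = boundaries)
}

# ---- trial generation ------------------------------------------------------

#' Generate one synthetic labeled trial
#'
#' Produces a 100 Hz, 20-channel recording following a protocol task list,
#' together with exact ground truth: mode segments with officially placed
#' boundaries, and per-foot contact/off events consistent with the insole
#' pressure channels. Identical `(config, protocol, subject)` inputs give
#' bit-identical output.
#'
#' @param config A [sim_config()].
#' @param protocol A protocol data frame as returned by
#'   [default_protocol()]; defaults to the standard task sequence for
#'   `config$set_variant`.
#' @param subject A subject template from [make_subject()]; defaults to the
#'   neutral (unperturbed) subject.
#' @param subject_id,trial_id Metadata strings.
#' @return A list with elements `recording` ([gait_recording()]) and
#'   `ground_truth` ([gait_ground_truth()]).
#' @export
generate_trial <- function(config = sim_config(), protocol = NULL,
                           subject = NULL, subject_id = "S1", trial_id = "T1") {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(protocol))
    protocol <- default_protocol(config$set_variant, config$steps_per_bout,
                                 config$stand_duration, config$turn_stand)
  if (is.null(subject)) subject <- .neutral_subject()
  tl <- .build_timeline(protocol, config)
  dt <- SAMPLE_PERIOD_S
  n <- floor(tl$duration / dt) + 1L
  t <- (seq_len(n) - 1L) * dt
  t_last <- t[n]
  sep <- config$mode_separation

  with_local_seed(config$seed, {
    trial_jitter <- matrix(stats::rnorm(72, 0, config$trial_mode_sd), 6, 12,
                           dimnames = list(rownames(.MODE_DELTA), NULL))
    press_jitter <- matrix(pmax(0.5, stats::rnorm(24, 1, 0.03)), 6, 4,
                           dimnames = list(rownames(.PRESS_FAC), NULL))
    noise <- if (config$noise_sd > 0)
      matrix(stats::rnorm(n * N_CHANNELS), n, N_CHANNELS) * config$noise_sd
    else matrix(0, n, N_CHANNELS)
    wander <- matrix(0, n, 12)
    if (config$wander_sd > 0) {
      phi <- exp(-SAMPLE_PERIOD_S / config$wander_tau)
      innov <- matrix(stats::rnorm(n * 12), n, 12) *
        (config$wander_sd * sqrt(1 - phi^2))
      for (c in 1:12) wander[, c] <- stats::filter(innov[, c], phi,
                                                   method = "recursive")
    }
    if (config$spike_rate > 0 && config$spike_amp > 0) {
      hit <- matrix(stats::runif(n * 12) < config$spike_rate * SAMPLE_PERIOD_S,
                    n, 12)
      spikes <- matrix(stats::runif(n * 12, 0.5, 1) *
                         sign(stats::runif(n * 12) - 0.5), n, 12) *
        config$spike_amp
      wander <- wander + hit * spikes
    }
  })

  delta_eff <- sep * .MODE_DELTA + subject$mode_jitter + trial_jitter

  ## pressures -----------------------------------------------------------
  press <- matrix(0, n, 8)
  stance_nom <- (1 - config$phase_fractions[["SW"]]) * config$cycle_duration
  standing_thresh <- 1.35 * stance_nom
  for (foot in c("M", "C")) {
    cols <- if (foot == "M") 1:4 else 5:8
    fs <- tl$steps[tl$steps$leg == foot, , drop = FALSE]
    stance_start <- c(0, fs$t_on)
    stance_end <- c(fs$t_off, t_last + dt)
    stance_mode <- c("S", fs$mode)
    from_landing <- c(FALSE, rep(TRUE, nrow(fs)))
    has_exit <- c(rep(TRUE, nrow(fs)), FALSE)
    for (k in seq_along(stance_start)) {
      idx <- which(t >= stance_start[k] - 1e-12 & t < stance_end[k] - 1e-12)
      if (!length(idx)) next
      dur <- stance_end[k] - stance_start[k]
      tau <- t[idx] - stance_start[k]
      m <- stance_mode[k]
      p_amps <- function(mode) .PRESS_AMP * (1 + sep * (.PRESS_FAC[mode, ] - 1)) *
        press_jitter[mode, ] * subject$press_fac
      amps <- p_amps(m)
      if (k > 1L && m != stance_mode[k - 1L]) {
        # first stance on new terrain: loading emphasized away from the
        # confusable sibling mode (matches the IMU entry emphasis)
        sib <- .MODE_SIBLING[[m]]
        if (!is.na(sib)) amps <- amps + .ENTRY_EMPH * (amps - p_amps(sib))
      }
      fac <- 1
      if (from_landing[k]) {
        # landings during a deceleration-to-stand blend toward the
        # dynamic-standing loading pattern (mirrors the fading IMU
        # envelope); the heel stays loaded, so contact detection holds
        js <- which(tl$stretches$start - 1e-9 <= stance_start[k] &
                      tl$stretches$end + 1e-9 >= stance_start[k])
        if (length(js)) {
          fac <- .sstep((tl$stretches$end[js[1]] - stance_start[k]) /
                          (0.9 * config$cycle_duration))
          amps_s <- .PRESS_AMP * (1 + sep * (.PRESS_FAC["S", ] - 1)) *
            press_jitter["S", ] * subject$press_fac
          amps <- fac * amps + (1 - fac) * amps_s
        }
      }
      if (dur > standing_thresh) {
        bump <- .stance_pressure(pmin(tau / stance_nom, 1), amps)
        # the closing landing of a bout settles onto the standing level
        # almost immediately, so analysis windows around it carry no
        # evolving heel-strike signature
        w <- if (from_landing[k]) .sstep(tau / (0.04 + 0.11 * fac)) else 1
        p <- (1 - w) * bump + w * rep(.PRESS_STAND, each = length(idx))
        if (has_exit[k]) p <- p * .sstep((stance_end[k] - t[idx]) / 0.03)
      } else {
        p <- .stance_pressure(tau / dur, amps)
      }
      press[idx, cols] <- p
    }
  }

  ## IMU ------------------------------------------------------------------
  imu <- matrix(0, n, 12)
  env <- numeric(n)
  afac <- rep(1, n)
  amp_s <- numeric(n)
  theta <- numeric(n)
  offsets <- matrix(0, n, 12)
  Tc <- config$cycle_duration
  all_steps <- tl$steps
  for (s in seq_len(nrow(tl$stretches))) {
    st <- tl$stretches[s, ]
    idx <- which(t >= st$start - 1e-12 & t <= st$end + 1e-12)
    if (!length(idx)) next
    fall <- if (st$amp < 1) 2.2 * Tc else 0.8 * Tc
    env[idx] <- .sstep((t[idx] - st$start) / (0.33 * Tc)) *
      .sstep((st$end - t[idx]) / fall)
    amp_s[idx] <- st$amp
    ssteps <- all_steps[all_steps$t_off >= st$start - 1e-9 &
                          all_steps$t_on <= st$end + 1e-9, , drop = FALSE]
    msteps <- ssteps[ssteps$leg == "M", , drop = FALSE]
    c_ref <- msteps$t_on[1]
    theta[idx] <- ((t[idx] - c_ref) / Tc) %% 1
    cur <- ssteps$mode[1]
    offsets[idx, ] <- rep(delta_eff[cur, ], each = length(idx))
    afac[idx] <- .MODE_AMPFAC[[cur]]
    changes <- which(ssteps$mode[-1] != ssteps$mode[-nrow(ssteps)]) + 1L
    for (ci in changes) {
      new <- ssteps$mode[ci]
      fs <- ssteps[ci, ]
      mf <- msteps[msteps$mode == new & msteps$t_off >= fs$t_off - 1e-9, ][1, ]
      sub <- idx[t[idx] >= min(fs$t_on, mf$t_off) - 0.15 - 1e-12]
      if (length(sub)) {
        # the first stride onto new terrain is deliberately emphasized
        # away from the confusable sibling mode (a cautious, exaggerated
        # entry step); the push sets in shortly after the swing begins
        # and decays back to the steady template over one cycle
        push <- .entry_push(new, sep)
        tt <- t[sub]
        # complete the measured-leg blend by 60% of its swing so the path
        # does not dwell near the sibling mode's template
        w <- .sstep((tt - mf$t_off) / (0.9 * (mf$t_on - mf$t_off)))
        if (fs$leg == "C") {
          # when the contralateral leg leads, stance posture already
          # adjusts partway as that leg lands on the new terrain
          w <- pmax(w, 0.35 * .sstep((tt - (fs$t_on - 0.15)) / 0.25))
        }
        decay <- .sstep((tt - mf$t_on) / Tc)
        eramp <- 1
        offsets[sub, ] <- (1 - w) %o% delta_eff[cur, ] +
          w %o% delta_eff[new, ] +
          (w * eramp * (1 - decay)) %o% push
        fa_t <- .entry_afac(new)
        afac[sub] <- (1 - w) * .MODE_AMPFAC[[cur]] + w * fa_t -
          w * decay * (fa_t - .MODE_AMPFAC[[new]])
      }
      cur <- new
    }
  }
  for (c in 1:12) {
    cyc <- sin(2 * pi * .IMU_FREQ[c] * theta + .IMU_PHI[c])
    imu[, c] <- .IMU_SCALE[c] *
      (subject$off[c] + env * offsets[, c] +
         env * amp_s * afac * subject$ampfac * .IMU_AMP[c] * cyc)
  }

  ## brief motion artifacts on one IMU module at a time ------------------
  if (config$artifact_rate > 0 && config$artifact_amp > 0) {
    with_local_seed(derive_seed(config$seed, 913L), {
      n_art <- stats::rpois(1, config$artifact_rate * t_last)
      for (a in seq_len(n_art)) {
        t0a <- stats::runif(1, 0, t_last)
        len <- stats::runif(1, config$artifact_ms[1], config$artifact_ms[2]) / 1000
        grp <- sample(0:2, 1)            # thigh / shank / foot module
        ch <- grp * 4L + 1:4
        offs <- config$artifact_amp * stats::runif(4, 0.7, 1.3) *
          sample(c(-1, 1), 4, replace = TRUE) * .IMU_SCALE[ch]
        sel <- which(t >= t0a & t < t0a + len)
        if (length(sel))
          imu[sel, ch] <- imu[sel, ch] + rep(offs, each = length(sel))
      }
    })
  }

  imu <- imu + wander * rep(.IMU_SCALE, each = n)
  channels <- cbind(press, imu)
  colnames(channels) <- gait_channels()
  noise[, 9:20] <- noise[, 9:20] * rep(.IMU_SCALE, each = n)
  channels <- channels + noise
  channels[, 1:8] <- pmax(channels[, 1:8], 0)

  ## ground truth ---------------------------------------------------------
  b <- tl$boundaries
  seg_mode <- c("S", b$to)
  seg_start <- c(0, b$time)
  seg_end <- c(b$time, t_last)
  keep <- seg_end > seg_start + 1e-9
  segments <- data.frame(mode = seg_mode[keep], start = seg_start[keep],
                         end = seg_end[keep], stringsAsFactors = FALSE)
  ms <- tl$steps[tl$steps$leg == "M", ]
  cs <- tl$steps[tl$steps$leg == "C", ]
  gt <- gait_ground_truth(
    mode_segments = segments,
    events_measured = list(foot_contact = ms$t_on, foot_off = ms$t_off),
    events_contralateral = list(foot_contact = cs$t_on, foot_off = cs$t_off),
    set_variant = config$set_variant)
  rec <- gait_recording(t, channels, subject_id = subject_id,
                        trial_id = trial_id, set_variant = config$set_variant)
  list(recording = rec, ground_truth = gt)
}

#' Generate a multi-subject cohort of trial pairs
#'
#' Each synthetic subject receives a fixed template perturbation
#' ([make_subject()]); each experiment pair consists of one Set-A and one
#' Set-B trial with independent per-trial jitter and noise. All seeds are
#' derived deterministically from `config$seed`.
#'
#' @param n_subjects,n_pairs_per_subject Cohort dimensions (both >= 1).
#' @param config A [sim_config()]; `set_variant` is overridden per trial.
#' @return A list of class `gait_cohort`: one element per subject with
#'   fields `subject_id`, `subject` and `pairs` (each pair a list with
#'   elements `A` and `B`, each a `list(recording, ground_truth)`).
#' @export
generate_cohort <- function(n_subjects, n_pairs_per_subject,
                            config = sim_config()) {
  stopifnot(n_subjects >= 1, n_pairs_per_subject >= 1)
  cohort <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    subj <- make_subject(derive_seed(config$seed, 7L, s), config)
    pairs <- vector("list", n_pairs_per_subject)
    for (p in seq_len(n_pairs_per_subject)) {
      pair <- list()
      for (v in c("A", "B")) {
        cfg <- config
        cfg$seed <- derive_seed(config$seed, s, p, if (v == "A") 1L else 2L)
        cfg$set_variant <- v
        pair[[v]] <- generate_trial(cfg, subject = subj,
                                    subject_id = sprintf("S%02d", s),
                                    trial_id = sprintf("S%02d_P%02d_%s", s, p, v))
      }
      pairs[[p]] <- pair
    }
    cohort[[s]] <- list(subject_id = sprintf("S%02d", s), subject = subj,
                        pairs = pairs)
  }
  structure(cohort, class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d subjects x %d pairs (%d trials)\n",
              length(x), length(x[[1]]$pairs), 2 * length(x) * length(x[[1]]$pairs)))
  invisible(x)
}

#' Flatten a cohort into a data frame of trials
#'
#' @param cohort A `gait_cohort`.
#' @return A data frame with columns `subject`, `pair`, `variant` and a
#'   list-column `trial`.
#' @export
cohort_trials <- function(cohort) {
  rows <- list()
  for (s in seq_along(cohort)) for (p in seq_along(cohort[[s]]$pairs))
    for (v in c("A", "B"))
      rows[[length(rows) + 1L]] <- list(subject = s, pair = p, variant = v,
                                        trial = cohort[[s]]$pairs[[p]][[v]])
  data.frame(subject = vapply(rows, `[[`, 0L, "subject"),
             pair = vapply(rows, `[[`, 0L, "pair"),
             variant = vapply(rows, `[[`, "", "variant"),
             trial = I(lapply(rows, `[[`, "trial")))
}
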