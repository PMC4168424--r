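#' Synthetic noisy decision-stream benchmark
#'
#' Generates a raw classifier decision stream with known ground truth for
#' benchmarking post-processing strategies in isolation from the sensor
#' pipeline: the true mode follows the standard protocol sequence, correct
#' decisions are emitted with high posterior confidence, and errors occur
#' in short bursts (as phase-classifier errors do) with moderate
#' confidence, at a configurable overall rate.
#'
#' @param seed Integer seed.
#' @param error_rate Target fraction of erroneous raw decisions.
#' @param burst_mean Mean error-burst length (decisions).
#' @param segment_s Range of segment durations in seconds.
#' @param rate_hz Decision rate (fixed 100 by the 10 ms window increment).
#' @return A list with `stream` (data frame `time`, `R`, `p`, `truth`) and
#'   `events` (transition scoring frame with `from`, `to`, `start`, `end`,
#'   `boundary`, `t_c`).
#' @export
simulate_decision_benchmark <- function(seed, error_rate = 0.05,
                                        burst_mean = 8, segment_s = c(2, 4),
                                        rate_hz = 100) {
  modes_seq <- c("S", "W", "SA", "W", "RD", "W", "S", "W", "RA", "W", "SD",
                 "W", "S")
  with_local_seed(seed, {
    dur <- stats::runif(length(modes_seq), segment_s[1], segment_s[2])
    ends <- cumsum(dur)
    starts <- c(0, ends[-length(ends)])
    n <- floor(ends[length(ends)] * rate_hz)
    time <- (seq_len(n) - 1L) / rate_hz
    truth <- modes_seq[findInterval(time, starts)]
    R <- truth
    p <- pmin(1, stats::runif(n, 0.94, 1.02))
    # error bursts
    rate <- error_rate / burst_mean
    bursts <- which(stats::runif(n) < rate)
    for (b in bursts) {
      len <- 1L + stats::rgeom(1, 1 / burst_mean)
      idx <- b:min(n, b + len - 1L)
      wrong <- sample(setdiff(gait_modes(), truth[b]), 1)
      R[idx] <- wrong
      p[idx] <- stats::runif(length(idx), 0.55, 0.92)
    }
    boundaries <- ends[-length(ends)]
    events <- data.frame(
      from = modes_seq[-length(modes_seq)], to = modes_seq[-1],
      start = boundaries - 0.2, end = boundaries + 0.6,
      boundary = boundaries, t_c = boundaries + 0.4)
    list(stream = data.frame(time = time, R = R, p = p, truth = truth,
                             stringsAsFactors = FALSE),
         events = events)
  })
}

#' Compare modified and original majority voting on a benchmark stream
#'
#' Runs both post-processing strategies on one benchmark replicate and
#' scores steady-period error rate and adjusted prediction time for each.
#'
#' @param bench Output of [simulate_decision_benchmark()].
#' @param config A [postproc_config()].
#' @param min_run,T_max Transition scoring settings.
#' @return One-row data frame with errors and APD (s) for both strategies.
#' @export
compare_postprocessing <- function(bench, config = postproc_config(),
                                   min_run = 31L, T_max = 2) {
  st <- bench$stream
  mod <- run_modified_voting(st$R, st$p, config)$D
  org <- run_original_voting(st$R, config$baseline_N)
  mask <- .steady_mask(st$time, bench$events)
  score <- function(D) {
    err <- mean(D[mask] != st$truth[mask])
    dec <- data.frame(time = st$time, D = D)
    oc <- lapply(seq_len(nrow(bench$events)), function(i)
      detect_transition(dec, bench$events[i, ], min_run))
    apd <- adjusted_prediction_time(
      data.frame(detected = vapply(oc, `[[`, TRUE, "detected"),
                 T_pre = vapply(oc, `[[`, 0, "T_pre")), T_max)
    c(err = err, APD = apd$APD, n_miss = apd$n_miss)
  }
  m <- score(mod); o <- score(org)
  data.frame(err_modified = m[["err"]], err_original = o[["err"]],
             APD_modified = m[["APD"]], APD_original = o[["APD"]],
             miss_modified = m[["n_miss"]], miss_original = o[["n_miss"]])
}
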