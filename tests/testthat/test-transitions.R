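test_that("every protocol trial yields twelve scored transition periods", {
  for (tr in list(clean_trial(), noisy_trial())) {
    ev <- critical_moments(transition_periods(tr$ground_truth),
                           tr$ground_truth)
    expect_equal(nrow(ev), 12)
    expect_true(all(ev$start < ev$end))
    expect_true(all(ev$t_c >= ev$start - 1e-9 & ev$t_c <= ev$end + 1e-9))
    types <- paste(ev$from, ev$to, sep = ">")
    expect_length(unique(types), 10)
  }
})

test_that("transition periods follow the period rules", {
  tr <- clean_trial()
  gt <- tr$ground_truth
  ev <- critical_moments(transition_periods(gt), gt)
  all_off <- sort(c(gt$events_measured$foot_off,
                    gt$events_contralateral$foot_off))
  for (i in seq_len(nrow(ev))) {
    if (ev$from[i] == "S") {
      # begins when either foot leaves the ground (= the boundary)
      expect_equal(ev$start[i], ev$boundary[i], tolerance = 1e-9)
    } else {
      # begins at a leading-leg foot-off
      expect_true(any(abs(all_off - ev$start[i]) < 1e-9))
    }
    if (ev$to[i] == "S") {
      # lasts exactly the final swing; critical moment = period end
      leg_ev <- if (leading_leg(ev$from[i], "S", gt$set_variant) == "M")
        gt$events_measured else gt$events_contralateral
      k <- which(abs(leg_ev$foot_off - ev$start[i]) < 1e-9)
      expect_length(k, 1)
      expect_equal(ev$end[i] - ev$start[i],
                   0.38 * 1.1, tolerance = 1e-6)
      expect_equal(ev$t_c[i], ev$end[i])
    } else {
      # critical moment is the first measured-foot contact in the period
      fc <- gt$events_measured$foot_contact
      expect_true(any(abs(fc - ev$t_c[i]) < 1e-9))
      expect_gte(ev$t_c[i], ev$start[i])
    }
  }
})

test_that("Set-A and Set-B critical moments differ by about one step", {
  a <- generate_trial(sim_config(seed = 17, set_variant = "A"))
  b <- generate_trial(sim_config(seed = 18, set_variant = "B"))
  ea <- critical_moments(transition_periods(a$ground_truth), a$ground_truth)
  eb <- critical_moments(transition_periods(b$ground_truth), b$ground_truth)
  # W>SA is measured-led in Set-A, unmeasured-led in Set-B: the gap from
  # period start to the critical moment grows by half a cycle
  ga <- ea$t_c[ea$to == "SA"] - ea$start[ea$to == "SA"]
  gb <- eb$t_c[eb$to == "SA"] - eb$start[eb$to == "SA"]
  expect_equal(gb - ga, 0.5 * 1.1, tolerance = 1e-6)
})

test_that("the detection rule scores runs per the consecutive-decision rule", {
  event <- data.frame(from = "W", to = "SA", start = 10, end = 11,
                      boundary = 10.2, t_c = 10.6)
  times <- seq(9.5, 12.5, by = 0.01)
  mk <- function(sa_from) data.frame(
    time = times, D = ifelse(times >= sa_from - 1e-9, "SA", "W"))
  # correct decisions from t_c - 0.4 onward: detected with T_pre = 0.4
  r <- detect_transition(mk(10.2), event)
  expect_true(r$detected)
  expect_equal(r$T_pre, 0.4, tolerance = 1e-9)
  # run starting after the critical moment: detected with negative T_pre
  r2 <- detect_transition(mk(10.72), event)
  expect_true(r2$detected)
  expect_equal(r2$T_pre, -0.12, tolerance = 1e-9)
  # no run of 31 within the period: missed
  d3 <- mk(10.2)
  d3$D[d3$time > 10.45 & d3$time < 10.5] <- "W"
  d3$D[d3$time > 10.8] <- "W"
  r3 <- detect_transition(d3, event)
  expect_false(r3$detected)
  # a run may complete beyond the period end
  d4 <- mk(10.95)
  r4 <- detect_transition(d4, event)
  expect_true(r4$detected)  # 31 consecutive reached after period end
  # a false decision after the run started, inside the period, spoils it
  d5 <- mk(10.3)
  d5$D[abs(d5$time - 10.9) < 1e-9] <- "RA"
  r5 <- detect_transition(d5, event)
  expect_true(r5$detected)          # run restarts after the false decision
  expect_equal(r5$t_pre, 10.91, tolerance = 1e-9)
})

test_that("adjusted prediction time satisfies its identity", {
  out <- data.frame(detected = c(TRUE, TRUE, FALSE),
                    T_pre = c(0.5, 0.3, NA))
  expect_equal(adjusted_prediction_time(out, T_max = 2)$APD, -1.2)
  out2 <- data.frame(detected = rep(TRUE, 2), T_pre = c(0.5, 0.3))
  expect_equal(adjusted_prediction_time(out2)$APD, 0.8)
  out3 <- data.frame(detected = rep(FALSE, 12), T_pre = NA_real_)
  expect_equal(adjusted_prediction_time(out3)$APD, -24)
  # randomized identity: APD = sum(T_pre detected) - T_max * misses
  set.seed(61)
  for (i in 1:25) {
    n <- sample(1:20, 1)
    oc <- data.frame(detected = runif(n) > 0.3,
                     T_pre = runif(n, -0.5, 1.5))
    oc$T_pre[!oc$detected] <- NA
    Tm <- runif(1, 0.5, 3)
    got <- adjusted_prediction_time(oc, Tm)
    expect_equal(got$APD,
                 sum(oc$T_pre[oc$detected]) - Tm * sum(!oc$detected),
                 tolerance = 1e-12)
    expect_equal(got$n, n)
  }
})

test_that("steady and transition periods partition the decision timeline", {
  tr <- noisy_trial()
  ev <- transition_periods(tr$ground_truth)
  times <- prepare_trial(tr)$windows$end_time
  mask <- gaitmode:::.steady_mask(times, ev)
  in_any <- rep(FALSE, length(times))
  for (i in seq_len(nrow(ev)))
    in_any <- in_any | (times >= ev$start[i] - 1e-9 &
                          times <= ev$end[i] + 1e-9)
  expect_identical(mask, !in_any)
  expect_equal(sum(mask) + sum(in_any), length(times))
  # transition periods do not overlap
  o <- order(ev$start)
  expect_true(all(ev$start[o][-1] >= ev$end[o][-nrow(ev)] - 1e-9))
})
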