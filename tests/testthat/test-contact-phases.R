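test_that("degenerate pressure inputs give degenerate contact series", {
  zero <- matrix(0, 200, 4)
  d <- detect_contact(zero, contact_config(theta_on = 0.3, theta_off = 0.15))
  expect_false(any(d))
  expect_length(attr(d, "foot_contact"), 0)

  high <- matrix(0.2, 200, 4)
  d2 <- detect_contact(high, contact_config(theta_on = 0.3, theta_off = 0.15))
  expect_true(all(d2))
  expect_length(attr(d2, "foot_off"), 0)
})

test_that("detected events match simulator ground truth within one sample", {
  tr <- generate_trial(sim_config(seed = 12, noise_sd = 0),
                       protocol = walk_only_protocol(10L))
  rec <- tr$recording
  ev <- tr$ground_truth$events_measured
  d <- detect_contact(rec$channels[, 1:4], t = rec$t)
  det <- contact_events(d)
  expect_length(det$foot_contact, length(ev$foot_contact))
  expect_length(det$foot_off, length(ev$foot_off))
  # compare on the sampling grid: ground-truth events rounded to nearest
  # sample (ties toward earlier), detections already grid-aligned
  snap <- function(x) round(x / 0.01 - 1e-9) * 0.01
  expect_lte(max(abs(snap(det$foot_contact) - snap(ev$foot_contact))), 0.0101)
  expect_lte(max(abs(snap(det$foot_off) - snap(ev$foot_off))), 0.0101)
})

test_that("the phase machine follows the canonical trigger sequence", {
  # measured contact at sample 1, contra off at 4, contra contact at 8,
  # measured off at 10 (12 samples in all)
  cm <- c(rep(TRUE, 9), rep(FALSE, 3))
  cc <- c(rep(TRUE, 3), rep(FALSE, 4), rep(TRUE, 5))
  ph <- segment_phases(cm, cc)
  expect_identical(as.character(ph),
                   c(rep("DS1", 3), rep("SS", 4), rep("DS2", 2), rep("SW", 3)))
  expect_length(attr(ph, "anomalies"), 0)
})

test_that("static standing holds the current double-stance state", {
  cm <- rep(TRUE, 50)
  cc <- rep(TRUE, 50)
  ph <- segment_phases(cm, cc)
  expect_true(all(ph == "DS1"))
})

test_that("impossible contralateral triggers are held and logged", {
  # contra contact while the measured foot is airborne
  cm <- c(rep(TRUE, 5), rep(FALSE, 10))
  cc <- c(rep(TRUE, 2), rep(FALSE, 6), rep(TRUE, 7))
  ph <- segment_phases(cm, cc)
  expect_gt(length(attr(ph, "anomalies")), 0)
  expect_true(all(ph[9:15] == "SW"))  # state held through the bad trigger
})

test_that("phase durations track the configured phase fractions", {
  tr <- generate_trial(sim_config(seed = 12, noise_sd = 0),
                       protocol = walk_only_protocol(10L))
  rec <- tr$recording
  gt <- tr$ground_truth
  cm <- detect_contact(rec$channels[, 1:4], t = rec$t)
  cc <- detect_contact(rec$channels[, 5:8], t = rec$t)
  ph <- segment_phases(cm, cc)
  mid <- rec$t > gt$events_measured$foot_contact[3] &
    rec$t < gt$events_measured$foot_contact[3] + 1.1
  counts <- table(factor(ph[mid], gait_phases()))
  expect_lt(max(abs(as.numeric(counts) / 110 - c(0.12, 0.38, 0.12, 0.38))),
            2 / 110)
})

test_that("sensor-driven phases match ground-truth phases on clean data", {
  tr <- clean_trial()
  rec <- tr$recording
  cm <- detect_contact(rec$channels[, 1:4], t = rec$t)
  cc <- detect_contact(rec$channels[, 5:8], t = rec$t)
  ph <- segment_phases(cm, cc)
  ph0 <- segment_phases(
    gaitmode:::.contact_from_events(tr$ground_truth$events_measured, rec$t),
    gaitmode:::.contact_from_events(tr$ground_truth$events_contralateral, rec$t))
  expect_gte(mean(as.character(ph) == as.character(ph0)), 0.99)
})

test_that("observed phase transitions respect the cycle order", {
  tr <- noisy_trial()
  rec <- tr$recording
  cm <- detect_contact(rec$channels[, 1:4], t = rec$t)
  cc <- detect_contact(rec$channels[, 5:8], t = rec$t)
  ph <- as.character(segment_phases(cm, cc))
  # within a walking bout, transitions only advance along the cycle
  seg <- tr$ground_truth$mode_segments
  wseg <- seg[seg$mode == "W", ][2, ]
  bout <- ph[rec$t > wseg$start + 0.2 & rec$t < wseg$end - 0.2]
  steps <- paste(bout[-length(bout)], bout[-1])[bout[-length(bout)] != bout[-1]]
  expect_true(all(steps %in% c("DS1 SS", "SS DS2", "DS2 SW", "SW DS1")))
})

test_that("window phase labels follow the strict more-than-half rule", {
  expect_identical(label_window_phase(rep(c("DS1", "SS"), c(8, 7))), "DS1")
  expect_identical(label_window_phase(rep(c("DS1", "SS"), c(7, 8))), "SS")
  expect_identical(label_window_phase(rep("SW", 15)), "SW")
  # exact split (even size) goes to the latter phase
  expect_identical(label_window_phase(rep(c("DS2", "SW"), c(5, 5))), "SW")
  # three phases: plurality wins
  expect_identical(label_window_phase(rep(c("DS1", "SS", "DS2"), c(4, 8, 3))), "SS")
  expect_error(label_window_phase(character(0)), "empty")
})
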