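test_that("official mode boundaries follow the three placement rules", {
  tr <- clean_trial()
  gt <- tr$ground_truth
  b <- mode_boundaries(gt)
  expect_equal(nrow(b), 12)
  all_off <- sort(c(gt$events_measured$foot_off,
                    gt$events_contralateral$foot_off))
  all_on <- sort(c(gt$events_measured$foot_contact,
                   gt$events_contralateral$foot_contact))
  for (i in seq_len(nrow(b))) {
    if (b$from[i] == "S") {
      # the instant either foot leaves the ground
      expect_true(any(abs(all_off - b$time[i]) < 1e-9))
    } else if (b$to[i] == "S") {
      # the closing swing-leg contact
      expect_true(any(abs(all_on - b$time[i]) < 1e-9))
    } else {
      # midpoint of the leading leg's swing
      leg <- leading_leg(b$from[i], b$to[i], gt$set_variant)
      ev <- if (leg == "M") gt$events_measured else gt$events_contralateral
      k <- which(ev$foot_off < b$time[i])
      off <- ev$foot_off[k[length(k)]]
      on <- ev$foot_contact[ev$foot_contact > off][1]
      expect_equal(b$time[i], (off + on) / 2, tolerance = 1e-9)
    }
  }
})

test_that("window counts follow n - size + 1 for arbitrary lengths", {
  tr <- clean_trial()
  n <- length(tr$recording$t)
  pw <- prepare_trial(tr)
  expect_equal(nrow(pw$windows), n - 15 + 1)
  for (ms in c(100, 150, 200)) {
    spec <- window_spec(ms)
    ph <- rep("DS1", n)
    win <- slide_windows(tr$recording, tr$ground_truth, spec, ph)
    expect_equal(nrow(win), n - ms / 10 + 1)
  }
})

test_that("window mode labels follow the strict more-than-half rule", {
  tr <- clean_trial()
  pw <- prepare_trial(tr)
  b <- mode_boundaries(tr$ground_truth)
  # around each boundary, the label flips exactly where the window center
  # crosses it: more than half the samples past the boundary => new mode
  for (i in seq_len(nrow(b))) {
    before <- pw$windows[pw$windows$end_time > b$time[i] - 0.04 &
                           pw$windows$end_time < b$time[i] + 0.0699, ]
    expect_true(all(before$mode == b$from[i]))
    after <- pw$windows[pw$windows$end_time > b$time[i] + 0.0801 &
                          pw$windows$end_time < b$time[i] + 0.15, ]
    expect_true(all(after$mode == b$to[i]))
  }
})

test_that("a recording shorter than one window is rejected", {
  tr <- clean_trial()
  short <- gait_recording(tr$recording$t[1:10],
                          tr$recording$channels[1:10, ])
  expect_error(slide_windows(short, tr$ground_truth, window_spec(150),
                             rep("DS1", 10)), "shorter")
})

test_that("training-set assembly pools, filters and partitions windows", {
  coh <- small_cohort()
  trials <- cohort_trials(coh)
  sub <- trials$trial[trials$subject == 1 & trials$pair == 1]
  both <- assemble_training_set(sub, c("A", "B"))
  only_a <- assemble_training_set(sub, "A")
  nA <- nrow(prepare_trial(sub[[1]])$windows)
  nB <- nrow(prepare_trial(sub[[2]])$windows)
  expect_equal(nrow(both$features), nA + nB)
  expect_equal(nrow(only_a$features), nA)
  # every window belongs to exactly one phase group
  expect_true(all(both$phase %in% gait_phases()))
  expect_equal(sum(table(both$phase)), nA + nB)
  expect_error(assemble_training_set(list(), "A"), "no trials")
})
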