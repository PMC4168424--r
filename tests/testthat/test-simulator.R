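test_that("the default protocol realizes the full task sequence", {
  for (v in c("A", "B")) {
    pr <- default_protocol(v)
    expect_identical(pr$mode[1], "S")
    expect_identical(pr$mode[nrow(pr)], "S")
    tr <- generate_trial(sim_config(seed = 3, set_variant = v))
    seg <- tr$ground_truth$mode_segments$mode
    trans <- paste(seg[-length(seg)], seg[-1], sep = ">")
    expected <- c("S>W", "W>SA", "SA>W", "W>RD", "RD>W", "W>S",
                  "W>RA", "RA>W", "W>SD", "SD>W")
    expect_true(all(expected %in% trans))
    expect_equal(sum(trans == "S>W"), 2)
    expect_equal(sum(trans == "W>S"), 2)
    expect_length(trans, 12)
  }
  # Set-B shares the mode sequence with Set-A
  a <- generate_trial(sim_config(seed = 3, set_variant = "A"))
  b <- generate_trial(sim_config(seed = 3, set_variant = "B"))
  expect_identical(a$ground_truth$mode_segments$mode,
                   b$ground_truth$mode_segments$mode)
})

test_that("identical seeds reproduce trials bit for bit", {
  t1 <- generate_trial(sim_config(seed = 99))
  t2 <- generate_trial(sim_config(seed = 99))
  expect_identical(t1$recording$channels, t2$recording$channels)
  expect_identical(t1$ground_truth, t2$ground_truth)
})

test_that("noise-free walking cycles are exactly periodic", {
  tr <- generate_trial(sim_config(seed = 4, noise_sd = 0),
                       protocol = walk_only_protocol(10L))
  rec <- tr$recording
  ev <- tr$ground_truth$events_measured
  # compare two consecutive mid-bout cycles, sampled at identical offsets
  # (early enough that the deceleration envelope has not begun)
  c1 <- which(rec$t >= ev$foot_contact[2])[1]
  per <- 110L  # 1.1 s cycle at 100 Hz
  cyc1 <- rec$channels[c1:(c1 + per - 1L), ]
  cyc2 <- rec$channels[(c1 + per):(c1 + 2L * per - 1L), ]
  expect_equal(cyc1, cyc2, tolerance = 1e-9)
})

test_that("measured-foot stance occupies the stance fraction of the cycle", {
  tr <- generate_trial(sim_config(seed = 4, noise_sd = 0),
                       protocol = walk_only_protocol(10L))
  rec <- tr$recording
  ev <- tr$ground_truth$events_measured
  sum4 <- rowSums(rec$channels[, 1:4])
  th <- 0.3 * stats::quantile(sum4, 0.9, names = FALSE)
  c1 <- ev$foot_contact[3]
  stance <- sum(sum4[rec$t >= c1 & rec$t < c1 + 1.1] > th)
  expect_lt(abs(stance / 110 - 0.62), 1.5 / 110)
})

test_that("cohorts have the right shape and valid ground truth", {
  coh <- small_cohort()
  expect_length(coh, 2)
  trials <- cohort_trials(coh)
  expect_equal(nrow(trials), 12)
  expect_equal(sum(trials$variant == "A"), 6)
  for (i in seq_len(nrow(trials)))
    expect_length(validate_ground_truth(trials$trial[[i]]$ground_truth,
                                        trials$trial[[i]]$recording), 0)
  # different subjects get different templates
  expect_false(identical(coh[[1]]$subject$off, coh[[2]]$subject$off))
})

test_that("a protocol with adjacent identical modes is rejected", {
  pr <- data.frame(mode = c("S", "W", "W", "S"),
                   kind = c("stand", "gait", "gait", "stand"),
                   steps = c(NA, 6L, 6L, NA), duration = c(2, NA, NA, 2))
  attr(pr, "set_variant") <- "A"
  expect_error(generate_trial(sim_config(seed = 1), protocol = pr),
               "adjacent identical modes")
})

test_that("config invariants are enforced", {
  expect_error(sim_config(phase_fractions = c(0.2, 0.3, 0.2, 0.2)), "sum to 1")
  expect_error(sim_config(noise_sd = -0.1), "noise_sd")
  expect_error(sim_config(steps_per_bout = 1), "steps_per_bout")
})

test_that("LDA separability is monotone in mode_separation", {
  acc <- vapply(c(0, 0.5, 1), function(sep) {
    tr <- generate_trial(sim_config(seed = 21, mode_separation = sep))
    pw <- prepare_trial(tr)
    fit <- fit_lda(pw$features, pw$windows$mode, lambda = 1e-3)
    mean(lda_predict(fit, pw$features)$class == pw$windows$mode)
  }, 0)
  expect_true(all(diff(acc) >= -0.005))
  expect_gt(acc[3], acc[1])
})
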