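test_that("decision weights rescale posteriors above the threshold", {
  expect_equal(decision_weight(0.5, 0.5), 0)
  expect_equal(decision_weight(1.0, 0.5), 1)
  expect_equal(decision_weight(0.8, 0.5), 0.6)
  expect_equal(decision_weight(0.49, 0.5), 0)
  expect_equal(decision_weight(c(0.5, 1, 0.8), 0.5), c(0, 1, 0.6))
  expect_error(decision_weight(1.2), "posterior")
})

test_that("voting values accumulate weighted votes per mode", {
  v <- voting_values(rep("W", 5), rep(1, 5))
  expect_equal(v$V[["W"]], 5)
  expect_equal(sum(v$V), 5)
  expect_identical(v$M_s, "W")

  v2 <- voting_values(c("W", "W", "SA", "SA", "SA"), c(1, 0.6, 0, 1, 0.6))
  expect_equal(v2$V[["W"]], 1.6)
  expect_equal(v2$V[["SA"]], 1.6)
  expect_true(v2$tie)

  v3 <- voting_values(c("W", "W", "SA", "SA", "SA"), c(1, 0.6, 0, 0.4, 0.2))
  expect_equal(v3$V[["W"]], 1.6)
  expect_equal(v3$V[["SA"]], 0.6)
  expect_identical(v3$M_s, "W")

  v4 <- voting_values(rep(c("W", "SA"), c(3, 2)), rep(0, 5))
  expect_true(all(v4$V == 0))
})

test_that("the final decision requires the top vote to clear gamma*N", {
  cfg <- postproc_config()
  st <- voting_values(rep("SA", 5), rep(1, 5))
  expect_identical(final_decision(st, "W", cfg), "SA")          # 5 > 3.75
  st0 <- voting_values(rep("SA", 5), rep(0, 5))
  expect_identical(final_decision(st0, "W", cfg), "W")          # hold
  stb <- voting_values(rep("SA", 5), rep(0.75, 5))
  expect_equal(stb$V_max, 3.75)
  expect_identical(final_decision(stb, "W", cfg), "W")          # strict >
})

test_that("modified voting is stable, suppressive and switches at 4 of 5", {
  cfg <- postproc_config()
  # constant confident stream passes through unchanged
  out <- run_modified_voting(rep("W", 30), rep(1, 30), cfg)
  expect_true(all(out$D == "W"))
  # a single flipped decision inside a confident run is suppressed,
  # whatever its confidence
  R <- rep("W", 20); R[10] <- "SA"
  p <- rep(1, 20)
  expect_true(all(run_modified_voting(R, p, cfg)$D == "W"))
  p[10] <- 0.3
  expect_true(all(run_modified_voting(R, p, cfg)$D == "W"))
  # a confident mode change is adopted when 4 of 5 buffered decisions
  # carry the new mode
  R2 <- rep(c("W", "SA"), c(10, 10))
  out2 <- run_modified_voting(R2, rep(1, 20), cfg)
  expect_identical(out2$D, rep(c("W", "SA"), c(13, 7)))
})

test_that("original voting is an unweighted plurality with tie hold", {
  expect_true(all(run_original_voting(rep("W", 30), 15) == "W"))
  # 8 W vs 7 SA in the buffer: plurality keeps W
  R <- rep(c("W", "SA"), c(8, 7))
  expect_identical(run_original_voting(R, 15)[15], "W")
  # ... and the switch happens as soon as the new mode outnumbers the old
  R2 <- c(rep("W", 10), rep("SA", 20))
  D2 <- run_original_voting(R2, 15)
  expect_identical(D2[17], "W")   # buffer 8 W / 7 SA
  expect_identical(D2[18], "SA")  # buffer 7 W / 8 SA
  # an exact tie between two modes retains the previous decision
  R3 <- c(rep("W", 15), rep("SA", 6), rep("RD", 3), "SA")
  D3 <- run_original_voting(R3, 15)
  # at k = 24 the buffer holds 6 W, 6 SA, 3 RD: tie -> hold previous (W)
  expect_identical(D3[24], "W")
  expect_identical(D3[25], "SA")
})

test_that("voting latency after a confident change is bounded", {
  cfg <- postproc_config()
  # ceil(gamma * N) + 1 = 5 decisions after the change at p = 1
  R <- rep(c("W", "RA"), c(40, 40))
  out <- run_modified_voting(R, rep(1, 80), cfg)
  first <- which(out$D == "RA")[1]
  expect_lte(first - 41 + 1, ceiling(cfg$gamma * cfg$N) + 1)
})

test_that("modified voting beats the original baseline on noisy streams", {
  res <- do.call(rbind, lapply(1:5, function(s)
    compare_postprocessing(simulate_decision_benchmark(s))))
  expect_true(all(res$err_modified <= res$err_original))
  expect_true(all(res$APD_modified >= res$APD_original))
})
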