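test_that("fitting recovers class structure from separated Gaussians", {
  set.seed(31)
  x <- matrix(rnorm(800), 400, 2)
  x[201:400, 1] <- x[201:400, 1] + 10
  labels <- rep(c("a", "b"), each = 200)
  fit <- fit_lda(x, labels, lambda = 0)
  mu_raw <- sweep(sweep(fit$means, 2, fit$scale, "*"), 2, fit$center, "+")
  expect_lt(max(abs(mu_raw - rbind(c(0, 0), c(10, 0)))), 0.3)
  expect_equal(sum(fit$prior), 1)
  # duplicating every sample leaves the fit essentially unchanged (only
  # the small-sample 1/(M-K) correction moves) and decisions unchanged
  fit2 <- fit_lda(rbind(x, x), c(labels, labels), lambda = 0)
  expect_equal(fit2$coef, fit$coef, tolerance = 5e-3)
  xt <- matrix(rnorm(100, 5), 50, 2)
  expect_identical(lda_predict(fit2, xt)$class, lda_predict(fit, xt)$class)
})

test_that("full shrinkage yields a spherical covariance", {
  set.seed(32)
  x <- matrix(rnorm(300), 100, 3) %*% matrix(c(2, 1, 0, 0, 1, 0, 0, 0, 0.2), 3)
  fit <- fit_lda(x, rep(c("a", "b"), 50), lambda = 1)
  expect_equal(fit$sigma, diag(3) * fit$sigma[1, 1], tolerance = 1e-12)
})

test_that("degenerate inputs are rejected", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(fit_lda(x, rep("a", 10)), "2 classes")
  expect_error(fit_lda(x, c(rep("a", 9), "b")), "fewer than 2")
  expect_error(fit_lda(x, rep(c("a", "b"), 5), lambda = 2), "lambda")
})

test_that("posteriors are calibrated softmax discriminants", {
  set.seed(33)
  x <- rbind(matrix(rnorm(100, -4), 100, 1), matrix(rnorm(100, 4), 100, 1))
  x <- cbind(x, rnorm(200))
  fit <- fit_lda(x, rep(c("a", "b"), each = 100), lambda = 0)
  p <- lda_posterior(fit, matrix(rnorm(40), 20, 2))
  expect_equal(unname(rowSums(p)), rep(1, 20), tolerance = 1e-12)
  # a point equidistant from both means splits the posterior evenly
  mid <- (fit$means[1, ] * fit$scale + fit$center +
            fit$means[2, ] * fit$scale + fit$center) / 2
  expect_equal(unname(lda_posterior(fit, mid)[1, ]), c(0.5, 0.5),
               tolerance = 0.02)
  # at a class mean with this separation the posterior is decisive
  mu_b <- fit$means[2, ] * fit$scale + fit$center
  pr <- lda_predict(fit, mu_b)
  expect_identical(pr$class, "b")
  expect_gt(pr$posterior, 0.99)
  expect_error(lda_posterior(fit, 1:3), "dimension mismatch")
})

test_that("predictions are invariant to affine rescaling of features", {
  set.seed(34)
  x <- matrix(rnorm(600), 200, 3)
  x[101:200, ] <- x[101:200, ] + rep(c(2, -1, 0.5), each = 100)
  labels <- rep(c("a", "b"), each = 100)
  xt <- matrix(rnorm(60), 20, 3)
  f1 <- fit_lda(x, labels, lambda = 1e-3)
  scl <- c(10, 0.1, 3); off <- c(5, -2, 0)
  x2 <- sweep(sweep(x, 2, scl, "*"), 2, off, "+")
  f2 <- fit_lda(x2, labels, lambda = 1e-3)
  xt2 <- sweep(sweep(xt, 2, scl, "*"), 2, off, "+")
  expect_identical(lda_predict(f1, xt)$class, lda_predict(f2, xt2)$class)
  expect_equal(lda_predict(f1, xt)$posterior, lda_predict(f2, xt2)$posterior,
               tolerance = 1e-9)
})

test_that("classification matches MASS::lda on a shared dataset", {
  set.seed(55)
  x <- iris3
  x <- rbind(iris3[, , 1], iris3[, , 2], iris3[, , 3])
  labels <- rep(c("set", "ver", "vir"), each = 50)
  fit <- fit_lda(x, labels, lambda = 0)
  ref <- MASS::lda(x, grouping = labels)
  expect_identical(lda_predict(fit, x)$class,
                   as.character(predict(ref, x)$class))
})

test_that("the phase bank fits one model per phase and routes by phase", {
  coh <- small_cohort()
  trials <- cohort_trials(coh)
  fit <- gaitlda(trials$trial[trials$subject == 1])
  expect_s3_class(fit, "gaitlda")
  expect_named(fit$models, gait_phases())
  for (ph in gait_phases())
    expect_setequal(fit$models[[ph]]$classes, gait_modes())
  # identical training data gives identical banks
  fit2 <- gaitlda(trials$trial[trials$subject == 1])
  expect_equal(coef(fit), coef(fit2), tolerance = 1e-12)
  # near-perfect recovery on clean, well-separated data
  tr <- clean_trial()
  pw <- prepare_trial(tr)
  fit3 <- gaitlda(list(tr))
  for (ph in gait_phases()) {
    idx <- which(pw$windows$phase == ph)
    acc <- mean(lda_predict(fit3$models[[ph]],
                            pw$features[idx, ])$class == pw$windows$mode[idx])
    expect_gte(acc, 0.97)
  }
})
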