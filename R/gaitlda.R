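#' Fit a phase-gated locomotion-mode classifier bank
#'
#' The central fitting function of the package: a two-level recognition
#' model in which plantar-pressure-driven gait phases (DS1, SS, DS2, SW)
#' gate one linear discriminant classifier each. Training windows are
#' segmented from the supplied trials, labeled by the official mode
#' boundaries, summarized by six time-domain features per channel and
#' pooled across trials and Set-A/Set-B variants before fitting the four
#' phase models.
#'
#' @param trials List of trials (`list(recording, ground_truth)`), or a
#'   `gait_training_set` from [assemble_training_set()].
#' @param variants Which set variants to pool for training.
#' @param window A [window_spec()].
#' @param contact A [contact_config()] (training phase streams use exact
#'   ground-truth events; the contact settings are stored for prediction).
#' @param lambda Covariance shrinkage passed to [fit_lda()].
#' @return An object of class `gaitlda` with one `lda_model` per phase.
#' @seealso [predict.gaitlda()], [evaluate_trial()], [loocv_evaluate()]
#' @export
gaitlda <- function(trials, variants = c("A", "B"), window = window_spec(),
                    contact = contact_config(), lambda = 1e-3) {
  ts <- if (inherits(trials, "gait_training_set")) trials
        else assemble_training_set(trials, variants, window, contact)
  phases <- gait_phases()
  models <- stats::setNames(vector("list", 4L), phases)
  counts <- matrix(0L, 4L, 6L, dimnames = list(phases, gait_modes()))
  for (ph in phases) {
    idx <- which(ts$phase == ph)
    if (!length(idx))
      stop("no training windows in phase ", ph, call. = FALSE)
    models[[ph]] <- fit_lda(ts$features[idx, , drop = FALSE], ts$mode[idx],
                            lambda)
    tab <- table(ts$mode[idx])
    counts[ph, names(tab)] <- as.integer(tab)
  }
  structure(list(models = models, window = ts$spec %||% window,
                 contact = contact, lambda = lambda, counts = counts,
                 n_trials = length(unique(ts$trial)), call = match.call()),
            class = "gaitlda")
}

# fit a bank directly from per-phase sufficient statistics (internal fast
# path used by cross-validation)
.bank_from_stats <- function(stats_by_phase, lambda, window, contact) {
  models <- lapply(stats_by_phase, fit_lda_stats, lambda = lambda)
  counts <- matrix(0L, 4L, 6L, dimnames = list(gait_phases(), gait_modes()))
  for (ph in names(models)) {
    ns <- vapply(stats_by_phase[[ph]], function(e) e$n, 0)
    counts[ph, names(ns)] <- as.integer(ns)
  }
  structure(list(models = models, window = window, contact = contact,
                 lambda = lambda, counts = counts, n_trials = NA_integer_,
                 call = NULL),
            class = "gaitlda")
}

#' @export
print.gaitlda <- function(x, ...) {
  cat(sprintf(
    "Phase-gated LDA locomotion-mode classifier (%d ms windows, lambda = %g)\n",
    x$window$size_ms, x$lambda))
  cat(sprintf("Training windows per phase: %s\n",
              paste(sprintf("%s=%d", rownames(x$counts), rowSums(x$counts)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
summary.gaitlda <- function(object, ...) {
  structure(list(counts = object$counts, window = object$window,
                 lambda = object$lambda,
                 classes = lapply(object$models, `[[`, "classes")),
            class = "summary.gaitlda")
}

#' @export
print.summary.gaitlda <- function(x, ...) {
  cat(sprintf("Phase-gated LDA bank: %d ms windows, shrinkage %g\n",
              x$window$size_ms, x$lambda))
  cat("Training window counts (phase x mode):\n")
  print(x$counts)
  invisible(x)
}

#' @export
coef.gaitlda <- function(object, ...) {
  lapply(object$models, function(m) {
    co <- rbind(intercept = m$intercept, m$coef)
    colnames(co) <- m$classes
    co
  })
}

#' Predict the decision stream for a trial
#'
#' Strictly causal replay of the online pipeline: sensor-driven contact
#' detection and phase segmentation, right-aligned windowing, feature
#' extraction, phase-routed LDA classification, and (optionally) majority
#'-vote smoothing. One decision is produced per 10 ms window increment;
#' no step reads samples later than the decision timestamp.
#'
#' @param object A fitted [gaitlda()] bank.
#' @param newdata One trial (`list(recording, ground_truth)`) or a bare
#'   `gait_recording` (phase detection never uses ground truth).
#' @param postproc `"modified"` (weighted vote), `"original"` (unweighted
#'   baseline) or `"none"` (raw decisions only).
#' @param config A [postproc_config()].
#' @param ... Unused.
#' @return A data frame of class `gaitlda_stream` with columns `time`,
#'   `phase`, `R` (raw decision), `p` (its posterior), `W` (vote weight)
#'   and `D` (smoothed decision; equals `R` for `postproc = "none"`).
#' @export
predict.gaitlda <- function(object, newdata,
                            postproc = c("modified", "original", "none"),
                            config = postproc_config(), ...) {
  postproc <- match.arg(postproc)
  rec <- if (inherits(newdata, "gait_recording")) newdata else newdata$recording
  cm <- detect_contact(rec$channels[, 1:4, drop = FALSE], object$contact, rec$t)
  cc <- detect_contact(rec$channels[, 5:8, drop = FALSE], object$contact, rec$t)
  ps <- segment_phases(cm, cc)
  size <- object$window$size
  feats <- window_features(rec$channels, size)
  phase <- .window_phases(as.character(ps), size)
  .stream_from_features(object, feats, phase, rec$t[seq.int(size, length(rec$t))],
                        postproc, config)
}

# classify pre-computed window features and smooth (shared fast path)
.stream_from_features <- function(bank, feats, phase, time, postproc, config) {
  n <- nrow(feats)
  R <- character(n); p <- numeric(n)
  for (ph in gait_phases()) {
    idx <- which(phase == ph)
    if (!length(idx)) next
    pr <- lda_predict(bank$models[[ph]], feats[idx, , drop = FALSE])
    R[idx] <- pr$class
    p[idx] <- pr$posterior
  }
  if (postproc == "modified") {
    v <- run_modified_voting(R, p, config)
    out <- data.frame(time = time, phase = phase, R = R, p = p, W = v$W,
                      D = v$D, stringsAsFactors = FALSE)
  } else if (postproc == "original") {
    D <- run_original_voting(R, config$baseline_N)
    out <- data.frame(time = time, phase = phase, R = R, p = p,
                      W = rep(1, n), D = D, stringsAsFactors = FALSE)
  } else {
    out <- data.frame(time = time, phase = phase, R = R, p = p,
                      W = decision_weight(p, config$p0), D = R,
                      stringsAsFactors = FALSE)
  }
  class(out) <- c("gaitlda_stream", class(out))
  out
}

#' Plot a decision stream
#'
#' Step plot of the smoothed decision stream over time (raw decisions as
#' points), with ground-truth mode boundaries optionally overlaid.
#'
#' @param x A `gaitlda_stream`.
#' @param gt Optional `gait_ground_truth` whose boundaries are drawn as
#'   dashed vertical lines.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gaitlda_stream <- function(x, gt = NULL, ...) {
  lv <- gait_modes()
  y <- match(x$D, lv)
  graphics::plot(x$time, y, type = "s", yaxt = "n", xlab = "time (s)",
                 ylab = "", ylim = c(0.5, 6.5), ...)
  graphics::points(x$time, match(x$R, lv), pch = ".", col = "grey50")
  graphics::axis(2, at = seq_along(lv), labels = lv, las = 1)
  if (!is.null(gt)) {
    b <- mode_boundaries(gt)
    graphics::abline(v = b$time, lty = 2, col = "grey60")
  }
  invisible(x)
}
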