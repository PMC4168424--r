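#' Classification accuracy over steady locomotion periods
#'
#' `CA = N_cor / N_total x 100%` over the decisions whose timestamps fall
#' in steady periods (outside every transition period).
#'
#' @param predicted,truth Aligned label vectors (one entry per decision).
#' @param steady_mask Logical vector selecting steady-period decisions.
#' @return List with `CA` (percent), `N_cor`, `N_total`.
#' @export
steady_accuracy <- function(predicted, truth, steady_mask) {
  stopifnot(length(predicted) == length(truth),
            length(steady_mask) == length(truth))
  if (!any(steady_mask)) stop("empty steady mask", call. = FALSE)
  n_tot <- sum(steady_mask)
  n_cor <- sum(predicted[steady_mask] == truth[steady_mask])
  list(CA = 100 * n_cor / n_tot, N_cor = n_cor, N_total = n_tot)
}

#' Confusion matrix as row percentages
#'
#' `c_ij = n_ij / n_i. x 100`: the percentage of decisions with true mode
#' i classified as mode j. Rows of modes absent from `truth` are `NA`.
#'
#' @param predicted,truth Label vectors (optionally pre-masked to steady
#'   periods).
#' @param counts If `TRUE` return raw counts instead of percentages.
#' @return A 6 x 6 matrix in canonical mode order.
#' @export
mode_confusion <- function(predicted, truth, counts = FALSE) {
  lv <- gait_modes()
  tab <- table(factor(truth, lv), factor(predicted, lv))
  m <- matrix(as.numeric(tab), 6, 6, dimnames = list(truth = lv, predicted = lv))
  if (counts) return(m)
  rs <- rowSums(m)
  pct <- 100 * m / rs
  pct[rs == 0, ] <- NA_real_
  pct
}

# steady mask for a vector of decision times given transition periods
.steady_mask <- function(times, periods) {
  mask <- rep(TRUE, length(times))
  for (i in seq_len(nrow(periods)))
    mask[times >= periods$start[i] - 1e-9 & times <= periods$end[i] + 1e-9] <- FALSE
  mask
}

#' Evaluate a fitted bank on one trial
#'
#' Runs the causal decision pipeline and scores it: steady-period
#' classification accuracy and confusion counts of the smoothed stream,
#' plus detection outcome and prediction time for every locomotion
#' transition.
#'
#' @param object A fitted [gaitlda()].
#' @param trial `list(recording, ground_truth)`.
#' @param postproc,config Passed to [predict.gaitlda()].
#' @param min_run Detection run length (see [detect_transition()]).
#' @param T_max Miss penalty in seconds.
#' @return List with `stream`, `CA`, `confusion` (counts), `outcomes`
#'   (per-transition data frame), `APD` (s), `n_miss`.
#' @export
evaluate_trial <- function(object, trial, postproc = "modified",
                           config = postproc_config(), min_run = 31L,
                           T_max = 2) {
  pw <- prepare_trial(trial, object$window, object$contact,
                      phase_source = "sensors")
  stream <- .stream_from_features(object, pw$features, pw$windows$phase,
                                  pw$windows$end_time, postproc, config)
  .score_stream(stream, pw$windows$mode, trial$ground_truth, min_run, T_max)
}

.score_stream <- function(stream, truth_mode, gt, min_run = 31L, T_max = 2) {
  periods <- critical_moments(transition_periods(gt), gt)
  mask <- .steady_mask(stream$time, periods)
  acc <- steady_accuracy(stream$D, truth_mode, mask)
  conf <- mode_confusion(stream$D[mask], truth_mode[mask], counts = TRUE)
  conf_raw <- mode_confusion(stream$R[mask], truth_mode[mask], counts = TRUE)
  outcomes <- periods
  outcomes$detected <- FALSE
  outcomes$t_pre <- outcomes$T_pre <- NA_real_
  outcomes$lead <- NA_character_
  for (i in seq_len(nrow(periods))) {
    r <- detect_transition(stream, periods[i, ], min_run)
    outcomes$detected[i] <- r$detected
    outcomes$t_pre[i] <- r$t_pre
    outcomes$T_pre[i] <- r$T_pre
    outcomes$lead[i] <- leading_leg(periods$from[i], periods$to[i],
                                    gt$set_variant)
  }
  apd <- adjusted_prediction_time(outcomes, T_max)
  list(stream = stream, CA = acc$CA, N_cor = acc$N_cor, N_total = acc$N_total,
       confusion = conf, confusion_raw = conf_raw, outcomes = outcomes,
       APD = apd$APD, n_miss = apd$n_miss)
}

# ---- cohort caching --------------------------------------------------------

# precompute windows, features, suffstats and transition periods per trial
.prep_cohort <- function(cohort, spec = window_spec(),
                         contact = contact_config(), need_stats = TRUE) {
  tr <- cohort_trials(cohort)
  caches <- vector("list", nrow(tr))
  for (i in seq_len(nrow(tr))) {
    trial <- tr$trial[[i]]
    train <- prepare_trial(trial, spec, contact, phase_source = "events")
    test <- prepare_trial(trial, spec, contact, phase_source = "sensors")
    stats <- NULL
    if (need_stats) {
      stats <- lapply(stats::setNames(gait_phases(), gait_phases()),
                      function(ph) {
        idx <- which(train$windows$phase == ph)
        lda_suffstats(train$features[idx, , drop = FALSE],
                      train$windows$mode[idx])
      })
    }
    caches[[i]] <- list(
      features = test$features,
      phase_test = test$windows$phase, phase_train = train$windows$phase,
      mode_train = train$windows$mode, mode_truth = test$windows$mode,
      time = test$windows$end_time, stats = stats,
      gt = trial$ground_truth)
  }
  tr$cache <- I(caches)
  tr
}

.combine_phase_stats <- function(a, b, sign = 1) {
  stats::setNames(lapply(gait_phases(), function(ph)
    .stats_combine(a[[ph]], b[[ph]], sign)), gait_phases())
}

# variant-filtered sum of per-trial phase stats over row indices
.sum_phase_stats <- function(prep, idx) {
  out <- NULL
  for (i in idx) {
    st <- prep$cache[[i]]$stats
    out <- if (is.null(out)) st else .combine_phase_stats(out, st)
  }
  out
}

#' Leave-one-pair-out cross-validation of the full pipeline
#'
#' For each subject, each experiment pair (one Set-A and one Set-B trial)
#' is held out in turn; the bank is trained on the subject's remaining
#' pairs (Set-A and Set-B pooled, optionally restricted) and both held-out
#' trials are replayed causally and scored. Results are averaged across
#' variants; the SEM of the headline metrics is computed across subjects.
#'
#' @param cohort A `gait_cohort` (each subject needs >= 2 pairs).
#' @param window,contact,lambda Model settings (see [gaitlda()]).
#' @param postproc,config Post-processing settings.
#' @param train_variants Variants pooled for training (`c("A","B")`,
#'   `"A"`, or `"B"`), supporting training-data combination experiments.
#' @param test_variants Variants evaluated.
#' @param min_run,T_max Transition scoring settings.
#' @param prep Optional precomputed cache from a previous call (internal).
#' @return An object of class `gaitmode_eval`: per-trial results,
#'   per-transition outcomes, pooled confusion counts and summary
#'   statistics.
#' @export
loocv_evaluate <- function(cohort, window = window_spec(),
                           contact = contact_config(), lambda = 1e-3,
                           postproc = "modified", config = postproc_config(),
                           train_variants = c("A", "B"),
                           test_variants = c("A", "B"),
                           min_run = 31L, T_max = 2, prep = NULL) {
  if (is.null(prep)) prep <- .prep_cohort(cohort, window, contact)
  subjects <- unique(prep$subject)
  pairs <- unique(prep$pair)
  if (length(pairs) < 2) stop("LOOCV needs at least 2 pairs", call. = FALSE)
  trial_rows <- list(); outcome_rows <- list()
  conf <- conf_raw <- matrix(0, 6, 6, dimnames = list(truth = gait_modes(),
                                                      predicted = gait_modes()))
  for (s in subjects) {
    s_rows <- which(prep$subject == s & prep$variant %in% train_variants)
    total <- .sum_phase_stats(prep, s_rows)
    for (p in pairs) {
      held_train <- which(prep$subject == s & prep$pair == p &
                            prep$variant %in% train_variants)
      fold <- total
      for (i in held_train)
        fold <- .combine_phase_stats(fold, prep$cache[[i]]$stats, -1)
      bank <- .bank_from_stats(fold, lambda, window, contact)
      test_rows <- which(prep$subject == s & prep$pair == p &
                           prep$variant %in% test_variants)
      for (i in test_rows) {
        ca <- prep$cache[[i]]
        stream <- .stream_from_features(bank, ca$features, ca$phase_test,
                                        ca$time, postproc, config)
        sc <- .score_stream(stream, ca$mode_truth, ca$gt, min_run, T_max)
        conf <- conf + sc$confusion
        conf_raw <- conf_raw + sc$confusion_raw
        trial_rows[[length(trial_rows) + 1L]] <- data.frame(
          subject = s, pair = p, variant = prep$variant[i], CA = sc$CA,
          APD = sc$APD, n_miss = sc$n_miss, stringsAsFactors = FALSE)
        oc <- sc$outcomes
        oc$subject <- s; oc$pair <- p; oc$variant <- prep$variant[i]
        outcome_rows[[length(outcome_rows) + 1L]] <- oc
      }
    }
  }
  trials <- do.call(rbind, trial_rows)
  outcomes <- do.call(rbind, outcome_rows)
  by_subj <- stats::aggregate(cbind(CA, APD) ~ subject, trials, mean)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  structure(list(
    trials = trials, outcomes = outcomes, confusion = conf,
    confusion_raw = conf_raw,
    CA = mean(by_subj$CA), CA_sem = sem(by_subj$CA),
    APD = mean(by_subj$APD), APD_sem = sem(by_subj$APD),
    n_miss = sum(trials$n_miss),
    n_folds = length(subjects) * length(pairs),
    settings = list(window = window, lambda = lambda, postproc = postproc,
                    train_variants = train_variants,
                    test_variants = test_variants)),
    class = "gaitmode_eval")
}

#' @export
print.gaitmode_eval <- function(x, ...) {
  cat(sprintf("Pipeline evaluation (%d folds, %s post-processing)\n",
              x$n_folds, x$settings$postproc))
  cat(sprintf("  steady-period CA: %.2f%% +/- %.2f%% (SEM across subjects)\n",
              x$CA, x$CA_sem))
  cat(sprintf("  APD: %.0f ms +/- %.0f ms; missed detections: %d / %d\n",
              1000 * x$APD, 1000 * x$APD_sem, x$n_miss, nrow(x$outcomes)))
  lead_means <- tapply(x$outcomes$T_pre[x$outcomes$detected],
                       x$outcomes$lead[x$outcomes$detected], mean)
  if (all(c("M", "C") %in% names(lead_means)))
    cat(sprintf("  mean T_pre: measured-led %.0f ms, unmeasured-led %.0f ms\n",
                1000 * lead_means[["M"]], 1000 * lead_means[["C"]]))
  invisible(x)
}

#' Performance sweeps over window size or training amount
#'
#' Fixed-split evaluations mirroring the window-size and training-amount
#' experiments: for each setting the bank is trained per subject on the
#' designated training pairs and scored on the held-out test pairs.
#'
#' @param cohort A `gait_cohort`.
#' @param sizes_ms Window sizes to sweep (multiples of 10 in 100-200).
#' @param train_pairs,test_pairs Pair indices per subject used for
#'   training and testing (defaults: first half / remainder).
#' @param contact,lambda,postproc,config,min_run,T_max As in
#'   [loocv_evaluate()].
#' @return Data frame with one row per setting: mean and SEM (across
#'   subjects) of steady CA and APD.
#' @export
sweep_window_size <- function(cohort, sizes_ms = seq(100, 200, 10),
                              train_pairs = NULL, test_pairs = NULL,
                              contact = contact_config(), lambda = 1e-3,
                              postproc = "modified",
                              config = postproc_config(),
                              min_run = 31L, T_max = 2) {
  n_pairs <- length(cohort[[1]]$pairs)
  if (is.null(train_pairs)) train_pairs <- seq_len(ceiling(n_pairs / 2))
  if (is.null(test_pairs)) test_pairs <- setdiff(seq_len(n_pairs), train_pairs)
  out <- lapply(sizes_ms, function(sz) {
    spec <- window_spec(sz)
    res <- .fixed_split_eval(cohort, spec, contact, lambda, postproc, config,
                             train_pairs, test_pairs, min_run, T_max)
    cbind(data.frame(size_ms = sz), res)
  })
  do.call(rbind, out)
}

#' @rdname sweep_window_size
#' @param n_pairs_seq Numbers of training pairs to sweep (per subject).
#' @param window A single [window_spec()] used for all settings.
#' @export
sweep_training_pairs <- function(cohort, n_pairs_seq = NULL,
                                 test_pairs = NULL, window = window_spec(),
                                 contact = contact_config(), lambda = 1e-3,
                                 postproc = "modified",
                                 config = postproc_config(),
                                 min_run = 31L, T_max = 2) {
  n_pairs <- length(cohort[[1]]$pairs)
  if (is.null(test_pairs)) test_pairs <- n_pairs
  avail <- setdiff(seq_len(n_pairs), test_pairs)
  if (is.null(n_pairs_seq)) n_pairs_seq <- seq_along(avail)
  prep <- .prep_cohort(cohort, window, contact)
  out <- lapply(n_pairs_seq, function(k) {
    res <- .fixed_split_eval(cohort, window, contact, lambda, postproc,
                             config, avail[seq_len(k)], test_pairs,
                             min_run, T_max, prep = prep)
    cbind(data.frame(n_train_pairs = k), res)
  })
  do.call(rbind, out)
}

.fixed_split_eval <- function(cohort, spec, contact, lambda, postproc, config,
                              train_pairs, test_pairs, min_run, T_max,
                              prep = NULL) {
  if (is.null(prep)) prep <- .prep_cohort(cohort, spec, contact)
  subjects <- unique(prep$subject)
  rows <- list()
  for (s in subjects) {
    tr_rows <- which(prep$subject == s & prep$pair %in% train_pairs)
    bank <- .bank_from_stats(.sum_phase_stats(prep, tr_rows), lambda, spec,
                             contact)
    te_rows <- which(prep$subject == s & prep$pair %in% test_pairs)
    for (i in te_rows) {
      ca <- prep$cache[[i]]
      stream <- .stream_from_features(bank, ca$features, ca$phase_test,
                                      ca$time, postproc, config)
      sc <- .score_stream(stream, ca$mode_truth, ca$gt, min_run, T_max)
      rows[[length(rows) + 1L]] <- data.frame(subject = s, CA = sc$CA,
                                              APD = sc$APD,
                                              n_miss = sc$n_miss)
    }
  }
  df <- do.call(rbind, rows)
  by_subj <- stats::aggregate(cbind(CA, APD) ~ subject, df, mean)
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  data.frame(CA = mean(by_subj$CA), CA_sem = sem(by_subj$CA),
             APD = mean(by_subj$APD), APD_sem = sem(by_subj$APD),
             n_miss = sum(df$n_miss))
}
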