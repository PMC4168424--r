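#' Post-processing configuration
#'
#' Parameters of the posterior-weighted majority vote used to smooth the
#' raw decision stream (voting depth `N = 5`, weight threshold
#' `p0 = 0.5`, decision threshold `gamma = 0.75`) and of the unweighted
#' majority-voting baseline (`baseline_N = 15`).
#'
#' @param N Voting depth (>= 1).
#' @param p0 Posterior threshold below which a decision gets zero weight.
#' @param gamma Fraction of `N` the top voting value must exceed before
#'   the smoothed decision may change.
#' @param baseline_N Depth of the unweighted baseline vote.
#' @return An object of class `postproc_config`.
#' @export
postproc_config <- function(N = 5L, p0 = 0.5, gamma = 0.75, baseline_N = 15L) {
  if (N < 1) stop("N must be >= 1", call. = FALSE)
  if (p0 < 0 || p0 >= 1) stop("p0 must be in [0, 1)", call. = FALSE)
  if (gamma <= 0 || gamma > 1) stop("gamma must be in (0, 1]", call. = FALSE)
  structure(list(N = as.integer(N), p0 = p0, gamma = gamma,
                 baseline_N = as.integer(baseline_N)),
            class = "postproc_config")
}

#' Weight of one decision for majority voting
#'
#' `W = (p - p0) / (1 - p0)` for `p >= p0`, else 0: confident decisions
#' vote with weight up to 1, decisions below the posterior threshold do
#' not vote at all.
#'
#' @param p Posterior probability (vectorized) in `[0, 1]`.
#' @param p0 Weight threshold.
#' @return Weights in `[0, 1]`.
#' @export
decision_weight <- function(p, p0 = 0.5) {
  if (any(p < 0 | p > 1)) stop("posterior must be in [0, 1]", call. = FALSE)
  ifelse(p >= p0, (p - p0) / (1 - p0), 0)
}

#' Voting values over a buffer of weighted decisions
#'
#' `V_j = sum_i W_i [R_i = M_j]` for each mode, with the largest voting
#' value and its mode extracted.
#'
#' @param R Character vector of the last `N` raw decisions.
#' @param W Their weights (same length).
#' @param modes Mode vocabulary (canonical order).
#' @return List with `V` (named numeric), `V_max`, `M_s` and `tie`.
#' @export
voting_values <- function(R, W, modes = gait_modes()) {
  stopifnot(length(R) == length(W))
  V <- vapply(modes, function(m) sum(W[R == m]), 0)
  V_max <- max(V)
  top <- which(V == V_max)
  list(V = V, V_max = V_max, M_s = modes[top[1]], tie = length(top) > 1L)
}

#' Final smoothed decision
#'
#' The smoothed decision changes to the top-voted mode only when its
#' voting value strictly exceeds `gamma * N` (and is unique); otherwise
#' the previous smoothed decision is held.
#'
#' @param state Result of [voting_values()].
#' @param D_prev Previous smoothed decision.
#' @param config A [postproc_config()].
#' @return A mode label.
#' @export
final_decision <- function(state, D_prev, config = postproc_config()) {
  if (!state$tie && state$V_max > config$gamma * config$N) state$M_s else D_prev
}

#' Smooth a raw decision stream by modified (weighted) majority voting
#'
#' Causal sliding buffer of the last `N` decisions; one smoothed decision
#' per incoming raw decision. Before `N` decisions accumulate the output
#' is the most recent raw decision, which also seeds the held value for
#' the first full vote.
#'
#' @param R Character vector of raw decisions.
#' @param p Posterior probability of each raw decision.
#' @param config A [postproc_config()].
#' @param modes Mode vocabulary.
#' @return Data frame with columns `R`, `p`, `W` and the smoothed
#'   decision `D`.
#' @export
run_modified_voting <- function(R, p, config = postproc_config(),
                                modes = gait_modes()) {
  n <- length(R)
  stopifnot(length(p) == n)
  W <- decision_weight(p, config$p0)
  N <- config$N
  D <- character(n)
  if (n == 0) return(data.frame(R = R, p = p, W = W, D = D))
  eta <- outer(R, modes, `==`)          # n x modes indicator
  VW <- eta * W
  cs <- apply(VW, 2, cumsum)
  cs <- rbind(matrix(0, 1, length(modes)), cs)
  thresh <- config$gamma * N
  D_prev <- NA_character_
  for (k in seq_len(n)) {
    if (k < N) {
      D[k] <- R[k]
    } else {
      if (k == N) D_prev <- if (k > 1L) R[k - 1L] else R[1L]
      V <- cs[k + 1L, ] - cs[k + 1L - N, ]
      V_max <- max(V)
      top <- which(V == V_max)
      D[k] <- if (length(top) == 1L && V_max > thresh) modes[top] else D_prev
      D_prev <- D[k]
    }
  }
  data.frame(R = R, p = p, W = W, D = D, stringsAsFactors = FALSE)
}

#' Smooth a raw decision stream by original (unweighted) majority voting
#'
#' Plurality over the last `baseline_N` raw decisions; ties hold the
#' previous smoothed decision. Initialization matches
#' [run_modified_voting()].
#'
#' @param R Character vector of raw decisions.
#' @param baseline_N Voting depth.
#' @param modes Mode vocabulary.
#' @return Character vector of smoothed decisions.
#' @export
run_original_voting <- function(R, baseline_N = 15L, modes = gait_modes()) {
  n <- length(R)
  N <- as.integer(baseline_N)
  D <- character(n)
  if (n == 0) return(D)
  eta <- outer(R, modes, `==`) + 0
  cs <- rbind(matrix(0, 1, length(modes)), apply(eta, 2, cumsum))
  D_prev <- NA_character_
  for (k in seq_len(n)) {
    if (k < N) {
      D[k] <- R[k]
    } else {
      if (k == N) D_prev <- if (k > 1L) R[k - 1L] else R[1L]
      V <- cs[k + 1L, ] - cs[k + 1L - N, ]
      V_max <- max(V)
      top <- which(V == V_max)
      D[k] <- if (length(top) == 1L) modes[top] else D_prev
      D_prev <- D[k]
    }
  }
  D
}
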