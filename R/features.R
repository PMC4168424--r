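#' Waveform length of a signal window
#'
#' The sum of absolute successive differences, a standard time-domain
#' activity feature.
#'
#' @param x Numeric vector of at least two samples.
#' @return A scalar.
#' @export
waveform_length <- function(x) {
  if (length(x) < 2) stop("waveform length needs at least 2 samples", call. = FALSE)
  sum(abs(diff(x)))
}

#' Six time-domain features of one analysis window
#'
#' Per channel: maximum, minimum, arithmetic mean, waveform length,
#' population (divide-by-n) standard deviation and root mean square,
#' concatenated in canonical channel order into a 120-value vector. The
#' population form of the standard deviation makes rms^2 = mean^2 + std^2
#' hold exactly.
#'
#' @param window Numeric matrix, samples x channels (one analysis window).
#' @return Named numeric vector of length `6 * ncol(window)`.
#' @export
extract_features <- function(window) {
  window <- as.matrix(window)
  if (!all(is.finite(window))) stop("non-finite values in window", call. = FALSE)
  out <- lapply(seq_len(ncol(window)), function(j) {
    x <- window[, j]
    m <- mean(x)
    msq <- mean(x^2)
    c(max = max(x), min = min(x), mean = m, wl = waveform_length(x),
      std = sqrt(max(msq - m^2, 0)), rms = sqrt(msq))
  })
  v <- unlist(out)
  cn <- colnames(window) %||% paste0("ch", seq_len(ncol(window)))
  names(v) <- paste(rep(cn, each = 6L), rep(FEATURE_NAMES, ncol(window)),
                    sep = ".")
  v
}

#' Feature matrix for all sliding windows of a trial
#'
#' Vectorized computation of [extract_features()] over every right-aligned
#' window of `size` samples (one window per sample from index `size`
#' onward), for all 20 channels.
#'
#' @param channels Samples x channels numeric matrix.
#' @param size Window size in samples.
#' @return Matrix of `n - size + 1` rows and `6 * ncol(channels)` columns,
#'   channel-major, features ordered max, min, mean, wl, std, rms.
#' @export
window_features <- function(channels, size) {
  channels <- as.matrix(channels)
  n <- nrow(channels)
  if (n < size) stop("fewer samples than one window", call. = FALSE)
  n_win <- n - size + 1L
  out <- matrix(0, n_win, 6L * ncol(channels))
  for (j in seq_len(ncol(channels))) {
    E <- stats::embed(channels[, j], size)  # row i = window ending at i+size-1
    mx <- do.call(pmax, as.data.frame(E))
    mn <- do.call(pmin, as.data.frame(E))
    m <- rowMeans(E)
    msq <- rowMeans(E * E)
    wl <- rowSums(abs(E[, -1L, drop = FALSE] - E[, -size, drop = FALSE]))
    std <- sqrt(pmax(msq - m * m, 0))
    rms <- sqrt(msq)
    out[, (j - 1L) * 6L + 1:6] <- cbind(mx, mn, m, wl, std, rms)
  }
  cn <- colnames(channels) %||% paste0("ch", seq_len(ncol(channels)))
  colnames(out) <- paste(rep(cn, each = 6L),
                         rep(FEATURE_NAMES, ncol(channels)), sep = ".")
  out
}
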