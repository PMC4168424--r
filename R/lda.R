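# Per-class sufficient statistics (n, column sums, raw cross-products) --
# additive across data subsets, so leave-one-pair-out refits are cheap.
lda_suffstats <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  out <- lapply(split(seq_len(nrow(x)), labels), function(idx) {
    xi <- x[idx, , drop = FALSE]
    list(n = length(idx), s = colSums(xi), c = crossprod(xi))
  })
  structure(out, d = ncol(x), class = "lda_suffstats")
}

.stats_combine <- function(a, b, sign = 1) {
  classes <- union(names(a), names(b))
  out <- stats::setNames(vector("list", length(classes)), classes)
  for (k in classes) {
    if (is.null(a[[k]])) { out[[k]] <- b[[k]]; next }
    if (is.null(b[[k]])) { out[[k]] <- a[[k]]; next }
    out[[k]] <- list(n = a[[k]]$n + sign * b[[k]]$n,
                     s = a[[k]]$s + sign * b[[k]]$s,
                     c = a[[k]]$c + sign * b[[k]]$c)
  }
  if (sign < 0) out <- Filter(function(e) e$n > 0, out)
  attributes(out) <- c(attributes(out),
                       list(d = attr(a, "d") %||% attr(b, "d")))
  class(out) <- "lda_suffstats"
  out
}

.order_classes <- function(classes) {
  if (all(classes %in% gait_modes()))
    intersect(gait_modes(), classes)
  else sort(classes)
}

# Fit from sufficient statistics: z-score standardization from the pooled
# training moments, class means, pooled within-class covariance with
# shrinkage toward a scaled identity.
fit_lda_stats <- function(stats, lambda = 1e-3) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]", call. = FALSE)
  classes <- .order_classes(names(stats))
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
  small <- classes[vapply(stats, function(e) e$n, 0)[classes] < 2]
  if (length(small))
    stop("class(es) with fewer than 2 samples: ", paste(small, collapse = ", "),
         call. = FALSE)
  d <- attr(stats, "d")
  M <- sum(vapply(stats, function(e) e$n, 0))
  tot_s <- Reduce(`+`, lapply(stats, `[[`, "s"))
  tot_c <- Reduce(`+`, lapply(stats, `[[`, "c"))
  center <- tot_s / M
  v <- diag(tot_c) / M - center^2          # population variance
  scale <- sqrt(pmax(v, 0))
  scale[scale < 1e-12] <- 1                # constant features left unscaled
  K <- length(classes)
  mu <- matrix(0, K, d, dimnames = list(classes, NULL))
  W <- matrix(0, d, d)
  prior <- numeric(K)
  for (i in seq_len(K)) {
    e <- stats[[classes[i]]]
    mu_k <- e$s / e$n
    W <- W + e$c - e$n * tcrossprod(mu_k)  # within-class scatter (raw scale)
    mu[i, ] <- (mu_k - center) / scale
    prior[i] <- e$n / M
  }
  W <- W / outer(scale, scale)             # standardized scatter
  sigma <- W / (M - K)
  sigma <- (sigma + t(sigma)) / 2
  if (lambda > 0)
    sigma <- (1 - lambda) * sigma + lambda * (sum(diag(sigma)) / d) * diag(d)
  ch <- tryCatch(chol(sigma), error = function(e)
    stop("pooled covariance is not positive definite (increase lambda)",
         call. = FALSE))
  A <- backsolve(ch, forwardsolve(t(ch), t(mu)))   # d x K = Sigma^-1 mu_k
  b <- -0.5 * colSums(t(mu) * A) + log(prior)
  structure(list(classes = classes, means = mu, sigma = sigma, lambda = lambda,
                 prior = prior, center = center, scale = scale,
                 coef = A, intercept = b, n = M),
            class = "lda_model")
}

#' Fit a linear discriminant classifier
#'
#' Gaussian classes with a shared covariance: empirical priors, class
#' means, and pooled within-class covariance
#' \eqn{\hat\Sigma = (M-K)^{-1} \sum_k \sum_{x \in k} (x-\mu_k)(x-\mu_k)^T},
#' regularized as \eqn{(1-\lambda)\hat\Sigma + \lambda (tr\hat\Sigma/d) I}.
#' Features are z-scored with training-set statistics before fitting; the
#' standardization is stored in the model, so predictions are unchanged by
#' any affine rescaling of the inputs.
#'
#' @param x Numeric feature matrix (samples x dimensions).
#' @param labels Class label per row (at least two classes, each with at
#'   least two samples).
#' @param lambda Shrinkage weight in `[0, 1]`.
#' @return An object of class `lda_model`.
#' @export
fit_lda <- function(x, labels, lambda = 1e-3) {
  fit_lda_stats(lda_suffstats(x, labels), lambda)
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d classes (%s), %d features, lambda = %g, n = %d\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              length(x$center), x$lambda, x$n))
  invisible(x)
}

#' Class posterior probabilities under a fitted discriminant model
#'
#' Softmax over the linear discriminant scores
#' \eqn{\delta_k(x) = x^T \Sigma^{-1}\mu_k - \mu_k^T \Sigma^{-1}\mu_k / 2 + \log\pi_k}.
#'
#' @param model An `lda_model`.
#' @param x Feature vector, or matrix with one row per observation.
#' @return Matrix of posterior probabilities (rows sum to 1), columns in
#'   the model's class order.
#' @export
lda_posterior <- function(model, x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(x) != length(model$center))
    stop(sprintf("feature dimension mismatch: model has %d, input has %d",
                 length(model$center), ncol(x)), call. = FALSE)
  z <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  sc <- z %*% model$coef + rep(model$intercept, each = nrow(z))
  sc <- sc - apply(sc, 1, max)
  e <- exp(sc)
  p <- e / rowSums(e)
  colnames(p) <- model$classes
  p
}

#' Classify observations with a fitted discriminant model
#'
#' Returns the maximum-posterior class and its posterior; exact ties are
#' broken by canonical mode order (the model's class order).
#'
#' @inheritParams lda_posterior
#' @return Data frame with columns `class` and `posterior`.
#' @export
lda_predict <- function(model, x) {
  p <- lda_posterior(model, x)
  j <- max.col(p, ties.method = "first")
  data.frame(class = model$classes[j],
             posterior = p[cbind(seq_len(nrow(p)), j)],
             stringsAsFactors = FALSE)
}
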