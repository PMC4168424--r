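# Brute-force pooled-covariance Gaussian Bayes classifier: the independent
# oracle against which the discriminant implementation is checked.
oracle_bayes_predict <- function(x_train, labels, x_test) {
  classes <- sort(unique(labels))
  mus <- lapply(classes, function(k)
    colMeans(x_train[labels == k, , drop = FALSE]))
  W <- Reduce(`+`, lapply(seq_along(classes), function(i) {
    xi <- x_train[labels == classes[i], , drop = FALSE]
    crossprod(sweep(xi, 2, mus[[i]]))
  }))
  sigma <- W / (nrow(x_train) - length(classes))
  si <- solve(sigma)
  prior <- as.numeric(table(factor(labels, classes))) / length(labels)
  unname(apply(x_test, 1, function(x) {
    ll <- vapply(seq_along(classes), function(i) {
      d <- x - mus[[i]]
      -0.5 * drop(t(d) %*% si %*% d) + log(prior[i])
    }, 0)
    classes[which.max(ll)]
  }))
}

# one random small well-conditioned instance (shared covariance classes)
oracle_instance <- function() {
  d <- sample(2:5, 1)
  K <- sample(2:3, 1)
  mus <- matrix(rnorm(K * d, sd = 3), K, d)
  A <- matrix(rnorm(d * d, sd = 0.3), d) + diag(d)
  labels <- rep(letters[1:K], each = 40)
  x <- do.call(rbind, lapply(1:K, function(k)
    matrix(rnorm(40 * d), 40, d) %*% A + rep(mus[k, ], each = 40)))
  list(x = x, labels = labels,
       x_test = matrix(rnorm(50 * d, sd = 3), 50, d))
}
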