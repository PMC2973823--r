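# Shared numerical core of the linear-nonlinear readouts: ridge-stabilised
# least squares for the linear stage and an exact threshold search for the
# static nonlinearity.

# Least squares y ~ X w + C with a small ridge penalty (weights only, not
# the constant) for numerical stability. Returns list(w, C, fitted).
ls_ridge_fit <- function(X, y, lambda = 1e-6) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  p <- ncol(X)
  Xa <- cbind(X, 1)
  G <- crossprod(Xa)
  if (p > 0) G[cbind(seq_len(p), seq_len(p))] <-
      G[cbind(seq_len(p), seq_len(p))] + lambda
  b <- crossprod(Xa, y)
  coef <- tryCatch(solve(G, b), error = function(e) {
    warning("singular design; regularizing the constant term as well")
    solve(G + diag(lambda, p + 1), b)
  })
  w <- coef[seq_len(p)]
  C <- coef[p + 1]
  list(w = w, C = C, fitted = as.numeric(X %*% w + C))
}

# Exact misclassification-minimising threshold for the rule
# "predict positive iff s >= theta". Scans all n+1 cut positions of the
# sorted linear outputs in O(n log n); the returned theta is the midpoint of
# the optimal gap (or just outside the data range at the extremes). False
# hits and false detections are weighted equally. Ties take the lowest cut.
threshold_search <- function(s, positive) {
  stopifnot(length(s) == length(positive), is.logical(positive))
  ord <- order(s)
  s <- s[ord]; pos <- positive[ord]
  n <- length(s)
  # errors at cut k (theta between s[k] and s[k+1]):
  #   positives with s < theta  +  negatives with s >= theta
  cum_pos <- c(0, cumsum(pos))
  cum_neg <- c(0, cumsum(!pos))
  errs <- cum_pos + (sum(!pos) - cum_neg)
  k <- which.min(errs) - 1L
  theta <- if (k == 0) s[1] - 1 else if (k == n) s[n] + 1
           else (s[k] + s[k + 1]) / 2
  list(theta = theta, train_errors = errs[k + 1L])
}
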