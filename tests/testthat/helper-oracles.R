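# Independent oracles and small fixture builders shared across the suite.

# Exhaustive-enumeration oracles for HMM likelihood and decoding: sum /
# argmax over all K^T state paths, computed from first principles (no use
# of the forward or Viterbi recursions).
enumerate_hmm <- function(model, X) {
  lB <- collarHMM:::emission_logdens(model, X)
  K <- length(model$states)
  Tn <- nrow(X)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  lp <- apply(paths, 1L, function(p) {
    v <- log(model$pi[p[1L]]) + lB[1L, p[1L]]
    if (Tn > 1L) for (t in 2:Tn)
      v <- v + log(model$A[p[t - 1L], p[t]]) + lB[t, p[t]]
    v
  })
  m <- max(lp)
  list(loglik = m + log(sum(exp(lp - m))),
       best = model$states[paths[which.max(lp), ]])
}

# A behavior_hmm object with arbitrary parameters, bypassing fitting.
manual_hmm <- function(pi, A, means, covs, states = NULL, features = NULL) {
  K <- nrow(means)
  D <- ncol(means)
  if (is.null(states)) states <- paste0("s", seq_len(K))
  if (is.null(features)) features <- paste0("f", seq_len(D))
  dimnames(A) <- list(states, states)
  dimnames(means) <- list(states, features)
  if (is.matrix(covs)) covs <- array(rep(covs, K), c(D, D, K))
  dimnames(covs) <- list(features, features, states)
  m <- structure(list(states = states, pi = stats::setNames(pi, states),
                      A = A, means = means, covs = covs,
                      features = features, ridge = 0, pseudocount = 0,
                      train_ids = "manual", n_obs = 0L, em = FALSE),
                 class = "behavior_hmm")
  collarHMM:::decorate_model(m)
}

# First-principles multivariate normal log-density (explicit inverse and
# determinant; independent of the package's Cholesky route).
mvtnorm_logdens_oracle <- function(X, mu, S) {
  D <- ncol(X)
  Si <- solve(S)
  ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  apply(X, 1L, function(x)
    -0.5 * (D * log(2 * pi) + ld + t(x - mu) %*% Si %*% (x - mu)))
}

random_hmm <- function(K, D, seed) {
  set.seed(seed)
  pi <- runif(K) + 0.1; pi <- pi / sum(pi)
  A <- matrix(runif(K * K) + 0.1, K, K); A <- A / rowSums(A)
  means <- matrix(rnorm(K * D, sd = 2), K, D)
  covs <- array(NA_real_, c(D, D, K))
  for (k in seq_len(K)) {
    M <- matrix(rnorm(D * D, sd = 0.5), D, D)
    covs[, , k] <- crossprod(M) + diag(D)
  }
  manual_hmm(pi, A, means, covs)
}

# Feature table with a perfectly separating feature and a pure-noise one.
separable_table <- function(n_per_class = 30, ids = c("a", "b"), seed = 1) {
  set.seed(seed)
  rows <- expand.grid(id = ids, label = c("lo", "hi"),
                      k = seq_len(n_per_class), stringsAsFactors = FALSE)
  data.frame(id = rows$id, window_start = seq_len(nrow(rows)),
             label = rows$label,
             seq_id = cumsum(c(TRUE, rows$id[-1] != rows$id[-nrow(rows)])),
             signal = ifelse(rows$label == "hi", 5, -5) + rnorm(nrow(rows), 0, 0.3),
             noise = rnorm(nrow(rows)),
             stringsAsFactors = FALSE)
}

# A constant-orientation trace: static (0, 0, 1) g, no movement.
constant_trace <- function(n = 200, rate = 10, id = "c1",
                           X = 0, Y = 0, Z = 1) {
  tr <- data.frame(id = id, time_s = (seq_len(n) - 1) / rate,
                   X = rep(X, n), Y = rep(Y, n), Z = rep(Z, n),
                   stringsAsFactors = FALSE)
  attr(tr, "rate_hz") <- rate
  tr
}

# Tiny labelled processed trace built directly (no simulator) for
# segmentation tests: one individual, given per-sample labels.
labelled_processed <- function(labels, rate = 10, id = "p1") {
  n <- length(labels)
  tr <- constant_trace(n, rate, id)
  pr <- process_trace(tr, span_s = 5)
  pr$label <- labels
  pr
}
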