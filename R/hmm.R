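# Supervised hidden Markov model with multivariate normal emissions over
# window-level feature vectors. Labels are the states, so maximum-likelihood
# fitting factorises into closed form: transition counts (with a
# pseudocount), run-initial frequencies, and per-class sample means and
# covariances (ridge-regularised). Likelihood evaluation uses the log-space
# forward recursion; decoding uses the Viterbi algorithm. An optional
# Baum-Welch refinement pass is available behind a flag.

## ---- multivariate normal helpers ----------------------------------------

# Cholesky-based log-densities of rows of X under N(mu, Sigma).
mvn_logdens <- function(X, mu, chol_S, logdet) {
  Z <- forwardsolve(t(chol_S), t(X) - mu)
  -0.5 * (ncol(X) * log(2 * pi) + logdet + colSums(Z^2))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# T x K matrix of per-window emission log-densities.
emission_logdens <- function(model, X) {
  K <- length(model$states)
  out <- matrix(NA_real_, nrow(X), K)
  for (k in seq_len(K)) {
    out[, k] <- mvn_logdens(X, model$means[k, ], model$.chol[[k]],
                            model$.logdet[k])
  }
  out
}

obs_matrix <- function(model, obs) {
  if (is.matrix(obs)) {
    if (is.null(colnames(obs))) {
      if (ncol(obs) != length(model$features))
        stop("observation matrix has ", ncol(obs), " columns; model expects ",
             length(model$features), call. = FALSE)
      colnames(obs) <- model$features
    }
    obs <- as.data.frame(obs)
  }
  miss <- setdiff(model$features, names(obs))
  if (length(miss))
    stop("observations lack model feature(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  as.matrix(obs[, model$features, drop = FALSE])
}

decorate_model <- function(model) {
  K <- length(model$states)
  model$.chol <- vector("list", K)
  model$.logdet <- numeric(K)
  for (k in seq_len(K)) {
    ch <- tryCatch(chol(model$covs[, , k]), error = function(e) NULL)
    if (is.null(ch)) {
      C <- stats::cov2cor(model$covs[, , k])
      diag(C) <- 0
      worst <- which(abs(C) == max(abs(C)), arr.ind = TRUE)[1L, ]
      stop(sprintf(
        "singular emission covariance for state '%s' even after ridge; most collinear feature pair: %s, %s",
        model$states[k], model$features[worst[1L]], model$features[worst[2L]]),
        call. = FALSE)
    }
    model$.chol[[k]] <- ch
    model$.logdet[k] <- 2 * sum(log(diag(ch)))
  }
  model
}

split_sequences <- function(table) {
  key <- if ("seq_id" %in% names(table)) {
    paste(table$id, table$seq_id, sep = "\r")
  } else {
    as.character(table$id)
  }
  split(seq_len(nrow(table)), factor(key, levels = unique(key)))
}

## ---- fitting -------------------------------------------------------------

#' Fit a supervised Gaussian-emission hidden Markov model
#'
#' Treats the training-class labels of a window-level feature table as the
#' hidden states and estimates all parameters in closed form: the
#' transition matrix from labelled transition counts within contiguous
#' window sequences (plus a pseudocount so rare behaviours never receive
#' zero transition mass), the initial distribution from run-initial labels,
#' and per-state multivariate normal emissions from class-wise sample means
#' and covariances with a small ridge on the diagonal (8-bit quantization
#' can make features near-constant within a class). Optionally refines the
#' parameters by Baum-Welch expectation-maximisation started from the
#' closed-form fit.
#'
#' @param table Feature table with columns \code{id}, \code{label},
#'   \code{seq_id} (contiguous-run id; absent means one run per individual)
#'   and the feature columns.
#' @param features Feature names to model (default: all feature columns).
#' @param pseudocount Added to every transition and initial count
#'   (default 1).
#' @param ridge Diagonal ridge added to each covariance; default
#'   \code{1e-6} times the mean within-class variance.
#' @param em If \code{TRUE}, run a Baum-Welch refinement pass.
#' @param em_tol,em_maxit Convergence tolerance on the log-likelihood and
#'   iteration cap for the refinement pass.
#' @return An object of class \code{"behavior_hmm"} with components
#'   \code{states}, \code{pi}, \code{A}, \code{means} (K x D),
#'   \code{covs} (D x D x K), \code{features}, \code{ridge},
#'   \code{train_ids}.
#' @seealso [predict.behavior_hmm()], [simulate.behavior_hmm()],
#'   [forward_loglik()], [viterbi_path()].
#' @export
behavior_hmm <- function(table, features = feature_columns(table),
                         pseudocount = 1, ridge = NULL,
                         em = FALSE, em_tol = 1e-6, em_maxit = 100) {
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  states <- sort(unique(table$label))
  K <- length(states)
  D <- length(features)
  X <- as.matrix(table[, features, drop = FALSE])
  counts <- table(factor(table$label, levels = states))
  starved <- states[counts < 2L]
  if (length(starved))
    stop("class(es) with fewer than 2 windows (covariance undefined): ",
         paste(starved, collapse = ", "),
         "; merge classes or provide more data", call. = FALSE)
  thin <- states[counts < D + 2L]
  if (length(thin))
    warning("class(es) with fewer than ", D + 2L, " windows for a ", D,
            "-feature covariance (ridge-stabilised, estimates will be ",
            "poor): ", paste(thin, collapse = ", "),
            "; consider merging classes or adding data", call. = FALSE)

  runs <- split_sequences(table)
  A_cnt <- matrix(0, K, K, dimnames = list(states, states))
  pi_cnt <- stats::setNames(numeric(K), states)
  for (idx in runs) {
    lab <- table$label[idx]
    pi_cnt[lab[1L]] <- pi_cnt[lab[1L]] + 1
    if (length(lab) > 1L) {
      from <- lab[-length(lab)]
      to <- lab[-1L]
      tt <- table(factor(from, levels = states), factor(to, levels = states))
      A_cnt <- A_cnt + unclass(tt)
    }
  }
  A <- A_cnt + pseudocount
  rs <- rowSums(A)
  if (any(rs == 0))
    stop("state(s) with no outgoing transitions and pseudocount 0: ",
         paste(states[rs == 0], collapse = ", "), call. = FALSE)
  A <- A / rs
  pi0 <- (pi_cnt + pseudocount) / sum(pi_cnt + pseudocount)

  means <- matrix(NA_real_, K, D, dimnames = list(states, features))
  covs <- array(NA_real_, c(D, D, K), dimnames = list(features, features, states))
  for (k in seq_len(K)) {
    Xi <- X[table$label == states[k], , drop = FALSE]
    means[k, ] <- colMeans(Xi)
    covs[, , k] <- stats::cov(Xi)
  }
  if (is.null(ridge)) {
    ridge <- 1e-6 * mean(apply(covs, 3L, function(S) mean(diag(S))))
    if (!is.finite(ridge) || ridge <= 0) ridge <- 1e-10
  }
  for (k in seq_len(K)) covs[, , k] <- covs[, , k] + diag(ridge, D)

  model <- structure(list(states = states, pi = pi0, A = A,
                          means = means, covs = covs, features = features,
                          ridge = ridge, pseudocount = pseudocount,
                          train_ids = unique(as.character(table$id)),
                          n_obs = nrow(table), em = em),
                     class = "behavior_hmm")
  model <- decorate_model(model)
  if (em) model <- baum_welch(model, table, tol = em_tol, maxit = em_maxit)
  model
}

## ---- forward / viterbi ---------------------------------------------------

#' Forward-algorithm log-likelihood
#'
#' Evaluates \eqn{\log p(x_{1:T})} for one observation sequence by the
#' log-space forward recursion (log-sum-exp at every step; no scaling
#' factors).
#'
#' @param model A \code{behavior_hmm}.
#' @param obs A numeric matrix (T x D) or data frame carrying the model's
#'   feature columns, in time order, from one contiguous sequence.
#' @return The log-likelihood (scalar). Zero-length input gives 0.
#' @export
forward_loglik <- function(model, obs) {
  X <- obs_matrix(model, obs)
  if (nrow(X) == 0L) return(0)
  lB <- emission_logdens(model, X)
  lA <- log(model$A)
  a <- log(model$pi) + lB[1L, ]
  if (nrow(X) > 1L) {
    for (t in 2:nrow(X)) {
      a <- apply(a + lA, 2L, logsumexp) + lB[t, ]
    }
  }
  logsumexp(a)
}

#' Viterbi decoding
#'
#' Returns the jointly most probable state path for one observation
#' sequence, computed in log space. Ties are broken toward the lower state
#' index (alphabetically first label).
#'
#' @inheritParams forward_loglik
#' @return Character vector of state labels (empty for empty input).
#' @export
viterbi_path <- function(model, obs) {
  X <- obs_matrix(model, obs)
  Tn <- nrow(X)
  if (Tn == 0L) return(character(0))
  K <- length(model$states)
  lB <- emission_logdens(model, X)
  lA <- log(model$A)
  delta <- log(model$pi) + lB[1L, ]
  back <- matrix(NA_integer_, Tn, K)
  if (Tn > 1L) {
    for (t in 2:Tn) {
      cand <- delta + lA                # K x K: from-state rows
      best_from <- apply(cand, 2L, which.max)
      delta <- cand[cbind(best_from, seq_len(K))] + lB[t, ]
      back[t, ] <- best_from
    }
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta)
  if (Tn > 1L) {
    for (t in (Tn - 1L):1L) path[t] <- back[t + 1L, path[t + 1L]]
  }
  model$states[path]
}

## ---- methods -------------------------------------------------------------

#' @export
print.behavior_hmm <- function(x, ...) {
  cat("Supervised Gaussian-emission hidden Markov model\n")
  cat(sprintf("  states   : %d (%s)\n", length(x$states),
              paste(x$states, collapse = ", ")))
  cat(sprintf("  features : %d (%s)\n", length(x$features),
              paste(x$features, collapse = ", ")))
  cat(sprintf("  fitted on: %d windows from %d individual(s)%s\n", x$n_obs,
              length(x$train_ids), if (isTRUE(x$em)) " (EM-refined)" else ""))
  cat("  self-transition probabilities:\n")
  st <- stats::setNames(round(diag(x$A), 3), x$states)
  print(st)
  invisible(x)
}

#' @export
summary.behavior_hmm <- function(object, ...) {
  cat("Transition matrix:\n")
  print(round(object$A, 3))
  cat("\nInitial distribution:\n")
  print(round(object$pi, 3))
  cat("\nState means:\n")
  print(round(object$means, 3))
  cat(sprintf("\nCovariance ridge: %.3g\n", object$ridge))
  invisible(object)
}

#' @export
coef.behavior_hmm <- function(object, ...) {
  list(pi = object$pi, A = object$A, means = object$means,
       covs = object$covs)
}

#' Log-likelihood of new observation sequences
#'
#' @param object A \code{behavior_hmm}.
#' @param newdata Feature table (with \code{id}/\code{seq_id} grouping) or
#'   a single observation matrix.
#' @param ... Unused.
#' @return Total forward log-likelihood, summed over contiguous sequences,
#'   as a \code{logLik} object.
#' @export
logLik.behavior_hmm <- function(object, newdata, ...) {
  ll <- if (is.data.frame(newdata) && "id" %in% names(newdata)) {
    sum(vapply(split_sequences(newdata), function(i)
      forward_loglik(object, newdata[i, , drop = FALSE]), numeric(1)))
  } else {
    forward_loglik(object, newdata)
  }
  K <- length(object$states); D <- length(object$features)
  npar <- (K - 1) + K * (K - 1) + K * D + K * D * (D + 1) / 2
  structure(ll, df = npar, class = "logLik")
}

#' Predict behaviour labels for held-out individuals
#'
#' Decodes each contiguous window sequence of \code{newdata} with the
#' Viterbi algorithm. Guards the leave-one-subject-out contract: it is an
#' error for any individual in \code{newdata} to have been in the training
#' set.
#'
#' @param object A \code{behavior_hmm}.
#' @param newdata Feature table; must contain \code{id} (and ideally
#'   \code{seq_id}) plus the model's features.
#' @param allow_overlap Set \code{TRUE} to bypass the train/test
#'   disjointness guard (e.g. for training-set diagnostics).
#' @param ... Unused.
#' @return \code{newdata} with a \code{pred} column of decoded labels.
#' @export
predict.behavior_hmm <- function(object, newdata, allow_overlap = FALSE, ...) {
  overlap <- intersect(unique(as.character(newdata$id)), object$train_ids)
  if (length(overlap) && !allow_overlap)
    stop("individual(s) present in both training and prediction data: ",
         paste(overlap, collapse = ", "),
         " (leave-one-subject-out requires disjoint sets)", call. = FALSE)
  out <- newdata
  out$pred <- NA_character_
  for (i in split_sequences(newdata)) {
    out$pred[i] <- viterbi_path(object, newdata[i, , drop = FALSE])
  }
  out
}

#' Simulate window sequences from a fitted model
#'
#' Draws hidden state paths from the model's initial and transition
#' distributions and emissions from the state-dependent multivariate
#' normals. Used for parameter-recovery checks and power analyses.
#'
#' @param object A \code{behavior_hmm}.
#' @param nsim Number of windows per sequence.
#' @param seed Optional integer seed.
#' @param n_seq Number of independent sequences.
#' @param ... Unused.
#' @return A feature table with \code{id} (\code{"sim01"}, ...),
#'   \code{seq_id}, true \code{label} and the feature columns.
#' @export
simulate.behavior_hmm <- function(object, nsim = 1, seed = NULL,
                                  n_seq = 1, ...) {
  if (!is.null(seed)) set.seed(seed)
  K <- length(object$states)
  D <- length(object$features)
  chol_list <- lapply(seq_len(K), function(k) chol(object$covs[, , k]))
  sims <- vector("list", n_seq)
  for (s in seq_len(n_seq)) {
    z <- integer(nsim)
    z[1L] <- sample.int(K, 1L, prob = object$pi)
    if (nsim > 1L) for (t in 2:nsim)
      z[t] <- sample.int(K, 1L, prob = object$A[z[t - 1L], ])
    E <- matrix(stats::rnorm(nsim * D), nsim, D)
    X <- matrix(NA_real_, nsim, D, dimnames = list(NULL, object$features))
    for (k in seq_len(K)) {
      i <- which(z == k)
      if (length(i))
        X[i, ] <- E[i, , drop = FALSE] %*% chol_list[[k]] +
          matrix(object$means[k, ], length(i), D, byrow = TRUE)
    }
    sims[[s]] <- cbind(
      data.frame(id = sprintf("sim%02d", s),
                 window_start = seq_len(nsim) - 1,
                 label = object$states[z], seq_id = s,
                 stringsAsFactors = FALSE),
      as.data.frame(X))
  }
  out <- do.call(rbind, sims)
  rownames(out) <- NULL
  out
}

## ---- Baum-Welch refinement ----------------------------------------------

# One forward-backward pass in log space; returns gamma, xi sums and the
# sequence log-likelihood.
forward_backward <- function(model, X) {
  Tn <- nrow(X)
  K <- length(model$states)
  lB <- emission_logdens(model, X)
  lA <- log(model$A)
  la <- matrix(NA_real_, Tn, K)
  lb <- matrix(0, Tn, K)
  la[1L, ] <- log(model$pi) + lB[1L, ]
  if (Tn > 1L) {
    for (t in 2:Tn)
      la[t, ] <- apply(la[t - 1L, ] + lA, 2L, logsumexp) + lB[t, ]
    for (t in (Tn - 1L):1L)
      lb[t, ] <- apply(lA + rep(lB[t + 1L, ] + lb[t + 1L, ], each = K),
                       1L, logsumexp)
  }
  ll <- logsumexp(la[Tn, ])
  lgamma_ <- la + lb - ll
  xi_sum <- matrix(0, K, K)
  if (Tn > 1L) {
    for (t in 1:(Tn - 1L)) {
      lxi <- outer(la[t, ], lB[t + 1L, ] + lb[t + 1L, ], "+") + lA - ll
      xi_sum <- xi_sum + exp(lxi)
    }
  }
  list(gamma = exp(lgamma_), xi = xi_sum, loglik = ll)
}

baum_welch <- function(model, table, tol = 1e-6, maxit = 100) {
  X_all <- obs_matrix(model, table)
  runs <- split_sequences(table)
  K <- length(model$states)
  D <- length(model$features)
  ll_old <- -Inf
  for (iter in seq_len(maxit)) {
    g_all <- matrix(NA_real_, nrow(X_all), K)
    xi_sum <- matrix(0, K, K)
    pi_sum <- numeric(K)
    ll <- 0
    for (idx in runs) {
      fb <- forward_backward(model, X_all[idx, , drop = FALSE])
      g_all[idx, ] <- fb$gamma
      xi_sum <- xi_sum + fb$xi
      pi_sum <- pi_sum + fb$gamma[1L, ]
      ll <- ll + fb$loglik
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
    model$pi <- stats::setNames(pi_sum / sum(pi_sum), model$states)
    A <- xi_sum / rowSums(xi_sum)
    dimnames(A) <- dimnames(model$A)
    model$A <- A
    for (k in seq_len(K)) {
      w <- g_all[, k]
      sw <- sum(w)
      mu <- colSums(X_all * w) / sw
      Xc <- sweep(X_all, 2L, mu)
      S <- crossprod(Xc * sqrt(w)) / sw + diag(model$ridge, D)
      model$means[k, ] <- mu
      model$covs[, , k] <- S
    }
    model <- decorate_model(model)
  }
  model$em_loglik <- ll_old
  model
}

## ---- serialization -------------------------------------------------------

#' Serialise / restore a fitted model as JSON
#'
#' Stores state labels, initial distribution, transition matrix, emission
#' means and covariances (row-major), feature names and the ridge at full
#' double precision; the round trip is exact.
#'
#' @param model A \code{behavior_hmm}.
#' @param path JSON file path.
#' @export
write_hmm_json <- function(model, path) {
  payload <- list(
    states = model$states,
    features = model$features,
    pi = unname(model$pi),
    A = as.vector(t(model$A)),
    means = as.vector(t(model$means)),
    covs = lapply(seq_along(model$states), function(k)
      as.vector(t(model$covs[, , k]))),
    ridge = model$ridge,
    pseudocount = model$pseudocount,
    train_ids = model$train_ids,
    n_obs = model$n_obs,
    em = isTRUE(model$em)
  )
  # 17 significant digits: lossless round trip for IEEE doubles
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_hmm_json
#' @export
read_hmm_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  states <- p$states
  features <- p$features
  K <- length(states); D <- length(features)
  A <- matrix(as.numeric(p$A), K, K, byrow = TRUE,
              dimnames = list(states, states))
  means <- matrix(as.numeric(p$means), K, D, byrow = TRUE,
                  dimnames = list(states, features))
  covs <- array(NA_real_, c(D, D, K),
                dimnames = list(features, features, states))
  cov_rows <- if (is.matrix(p$covs)) asplit(p$covs, 1L) else p$covs
  for (k in seq_len(K))
    covs[, , k] <- matrix(as.numeric(cov_rows[[k]]), D, D, byrow = TRUE)
  model <- structure(list(states = states,
                          pi = stats::setNames(as.numeric(p$pi), states),
                          A = A, means = means, covs = covs,
                          features = features, ridge = p$ridge,
                          pseudocount = p$pseudocount,
                          train_ids = p$train_ids, n_obs = p$n_obs,
                          em = isTRUE(p$em)),
                     class = "behavior_hmm")
  decorate_model(model)
}
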