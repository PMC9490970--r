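# Supervised fitting, forward likelihood, Viterbi decoding, EM refinement,
# serialization.

test_that("transition counting matches hand tallies", {
  tab <- data.frame(id = "a", window_start = 1:4, seq_id = 1,
                    label = c("A", "A", "B", "B"),
                    f1 = c(0, 0.1, 5, 5.1), f2 = c(1, 0.9, -1, -1.1))
  m <- suppressWarnings(behavior_hmm(tab, c("f1", "f2"), pseudocount = 0))
  expect_equal(unname(m$A["A", ]), c(0.5, 0.5))
  expect_equal(unname(m$A["B", ]), c(0, 1))
  expect_equal(unname(m$pi), c(1, 0))      # single run starting in A
  # with pseudocount 1 every transition has positive mass
  m1 <- suppressWarnings(behavior_hmm(tab, c("f1", "f2"), pseudocount = 1))
  expect_true(all(m1$A > 0))
})

test_that("rows of the transition matrix and pi stay on the simplex", {
  for (pc in c(0, 0.5, 1, 3)) {
    set.seed(pc * 10 + 1)
    tab <- data.frame(id = rep(c("a", "b"), each = 30),
                      window_start = 1:60, seq_id = rep(1:2, each = 30),
                      label = sample(c("x", "y", "z"), 60, replace = TRUE),
                      f1 = rnorm(60), f2 = rnorm(60))
    m <- behavior_hmm(tab, c("f1", "f2"), pseudocount = pc)
    expect_equal(unname(rowSums(m$A)), rep(1, 3), tolerance = 1e-9)
    expect_equal(sum(m$pi), 1, tolerance = 1e-9)
    expect_true(all(m$A >= 0) && all(m$pi >= 0))
  }
})

test_that("a single-class fit degenerates to A = [[1]]", {
  set.seed(7)
  tab <- data.frame(id = "a", window_start = 1:20, seq_id = 1,
                    label = "only", f1 = rnorm(20), f2 = rnorm(20))
  m <- behavior_hmm(tab, c("f1", "f2"))
  expect_equal(unname(m$A), matrix(1))
  expect_equal(unname(m$pi), 1)
  # K = 1 likelihood is the sum of per-window Gaussian log-densities
  X <- as.matrix(tab[, c("f1", "f2")])
  ll <- forward_loglik(m, X)
  dens <- mvtnorm_logdens_oracle(X, m$means[1, ], m$covs[, , 1])
  expect_equal(ll, sum(dens), tolerance = 1e-10)
  # K = 1 Viterbi labels everything with the single state
  expect_equal(viterbi_path(m, X), rep("only", 20))
})

test_that("starved and thin classes are flagged with actionable advice", {
  set.seed(5)
  tab <- data.frame(id = "a", window_start = 1:30, seq_id = 1,
                    label = c(rep("big", 29), "lone"),
                    f1 = rnorm(30), f2 = rnorm(30))
  expect_error(behavior_hmm(tab, c("f1", "f2")), "lone")
  tab$label <- c(rep("big", 27), rep("tiny", 3))
  expect_warning(behavior_hmm(tab, c("f1", "f2")), "tiny")
})

test_that("forward log-likelihood matches exhaustive enumeration", {
  for (s in 1:12) {
    K <- 1 + (s %% 3)
    Tn <- 2 + (s %% 6)
    model <- random_hmm(K, D = 2, seed = 100 + s)
    set.seed(200 + s)
    X <- matrix(rnorm(Tn * 2, sd = 2), Tn, 2)
    oracle <- enumerate_hmm(model, X)
    expect_equal(forward_loglik(model, X), oracle$loglik, tolerance = 1e-8)
  }
})

test_that("Viterbi matches the exhaustive argmax and breaks ties low", {
  for (s in 1:12) {
    K <- 2 + (s %% 2)
    Tn <- 2 + (s %% 5)
    model <- random_hmm(K, D = 2, seed = 300 + s)
    set.seed(400 + s)
    X <- matrix(rnorm(Tn * 2, sd = 2), Tn, 2)
    oracle <- enumerate_hmm(model, X)
    expect_equal(viterbi_path(model, X), unname(oracle$best))
  }
  # two indistinguishable states: the lower-indexed label wins everywhere
  m <- manual_hmm(pi = c(0.5, 0.5), A = matrix(0.5, 2, 2),
                  means = matrix(c(0, 0), 2, 1), covs = diag(1))
  expect_equal(viterbi_path(m, matrix(c(0.3, -0.2))), c("s1", "s1"))
})

test_that("empty sequences decode to empty paths with zero log-likelihood", {
  m <- random_hmm(2, 2, seed = 1)
  X <- matrix(numeric(0), 0, 2)
  expect_equal(viterbi_path(m, X), character(0))
  expect_equal(forward_loglik(m, X), 0)
})

test_that("dimension mismatches are argument errors", {
  m <- random_hmm(2, 3, seed = 2)
  expect_error(forward_loglik(m, matrix(0, 4, 2)), "columns")
  df <- data.frame(f1 = 1, bogus = 2)
  expect_error(forward_loglik(m, df), "feature")
})

test_that("decoding on well-separated sticky states is near-perfect", {
  A <- matrix(c(0.95, 0.03, 0.02,
                0.03, 0.95, 0.02,
                0.02, 0.03, 0.95), 3, 3, byrow = TRUE)
  mu <- matrix(c(0, 0, 6, 0, 0, 6), 3, 2, byrow = TRUE)  # >= 6 sd apart
  truth_model <- manual_hmm(pi = rep(1 / 3, 3), A = A, means = mu,
                            covs = diag(2))
  sim <- simulate(truth_model, nsim = 2000, seed = 42)
  pred <- viterbi_path(truth_model, as.matrix(sim[, c("f1", "f2")]))
  expect_gte(mean(pred == sim$label), 0.95)
})

test_that("supervised refit recovers the generating parameters (self-consistency)", {
  A <- matrix(c(0.90, 0.06, 0.04,
                0.05, 0.90, 0.05,
                0.04, 0.06, 0.90), 3, 3, byrow = TRUE)
  mu <- matrix(c(0, 0, 3, 1, -1, 3), 3, 2, byrow = TRUE)
  truth <- manual_hmm(pi = rep(1 / 3, 3), A = A, means = mu, covs = diag(2))
  sim <- simulate(truth, nsim = 3000, seed = 7)
  fit <- behavior_hmm(sim, c("f1", "f2"), pseudocount = 1)
  states <- fit$states
  n_from <- table(factor(sim$label[-nrow(sim)], levels = states))
  for (i in seq_len(3)) for (j in seq_len(3)) {
    p <- truth$A[i, j]
    se <- sqrt(p * (1 - p) / n_from[[truth$states[i]]])
    expect_lt(abs(fit$A[truth$states[i], truth$states[j]] - p), 3 * se + 0.01)
  }
})

test_that("the Viterbi prediction honours sequence structure", {
  # sticky two-state chain with overlapping emissions: order matters
  A <- matrix(c(0.97, 0.03, 0.03, 0.97), 2, 2, byrow = TRUE)
  truth <- manual_hmm(pi = c(0.5, 0.5), A = A,
                      means = matrix(c(0, 1.2), 2, 1), covs = diag(1) * 1)
  sim <- simulate(truth, nsim = 400, seed = 9)
  X <- as.matrix(sim[, "f1", drop = FALSE])
  p1 <- viterbi_path(truth, X)
  set.seed(10)
  perm <- sample(nrow(X))
  p2 <- viterbi_path(truth, X[perm, , drop = FALSE])
  # shuffling windows changes decoded labels (serial dependence is real)
  expect_gt(mean(p1[perm] != p2), 0.01)
})

test_that("predict() enforces the leave-one-subject-out guard", {
  tab <- separable_table(n_per_class = 20, ids = c("a", "b"), seed = 3)
  m <- behavior_hmm(tab[tab$id == "a", ], c("signal", "noise"))
  expect_error(predict(m, tab[tab$id == "a", ]), "training and prediction")
  out <- predict(m, tab[tab$id == "b", ])
  expect_true(all(out$pred %in% m$states))
  expect_gte(mean(out$pred == out$label), 0.95)
  # the guard can be bypassed explicitly for training diagnostics
  expect_silent(predict(m, tab[tab$id == "a", ], allow_overlap = TRUE))
})

test_that("EM refinement does not degrade the training likelihood", {
  tab <- separable_table(n_per_class = 40, ids = c("a", "b"), seed = 11)
  m0 <- behavior_hmm(tab, c("signal", "noise"), em = FALSE)
  m1 <- behavior_hmm(tab, c("signal", "noise"), em = TRUE)
  ll0 <- as.numeric(logLik(m0, tab))
  ll1 <- as.numeric(logLik(m1, tab))
  expect_gte(ll1, ll0 - 1e-6)
})

test_that("JSON serialization round-trips the model exactly", {
  tab <- separable_table(n_per_class = 25, ids = c("a", "b"), seed = 13)
  m <- behavior_hmm(tab, c("signal", "noise"))
  f <- withr::local_tempfile(fileext = ".json")
  write_hmm_json(m, f)
  back <- read_hmm_json(f)
  expect_equal(back$pi, m$pi, tolerance = 1e-15)
  expect_equal(back$A, m$A, tolerance = 1e-15)
  expect_equal(back$means, m$means, tolerance = 1e-15)
  expect_equal(back$covs, m$covs, tolerance = 1e-15)
  expect_identical(back$states, m$states)
  expect_identical(back$features, m$features)
  # decoded paths agree exactly
  X <- as.matrix(tab[, c("signal", "noise")])
  expect_identical(viterbi_path(back, X), viterbi_path(m, X))
})

test_that("model methods print, summarise and expose coefficients", {
  tab <- separable_table(n_per_class = 20, ids = c("a", "b"), seed = 15)
  m <- behavior_hmm(tab, c("signal", "noise"))
  expect_output(print(m), "hidden Markov model")
  expect_output(summary(m), "Transition matrix")
  cf <- coef(m)
  expect_named(cf, c("pi", "A", "means", "covs"))
  sim <- simulate(m, nsim = 50, seed = 1, n_seq = 2)
  expect_equal(nrow(sim), 100L)
  expect_setequal(unique(sim$seq_id), 1:2)
})
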