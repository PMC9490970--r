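# Random-forest and radial-kernel SVM window classifiers. These are the
# pipeline's off-the-shelf comparators: randomForest and e1071 provide the
# learners; this file fixes the tuning contracts (grids, per-fold
# standardization, seeding) and the leave-one-subject-out tuning loop.

label_factor <- function(x, levels) factor(as.character(x), levels = levels)

#' Random-forest factory for wrapper selection
#'
#' Returns a \code{model_factory} closure for
#' [forward_feature_selection()]: \code{function(train, features)} fitting
#' a random forest with the given tree count.
#'
#' @param ntree Trees per forest.
#' @param mtry Variables tried per split; default
#'   \code{floor(sqrt(length(features)))}.
#' @param seed Seed set before each fit for determinism.
#' @return A factory function.
#' @export
rf_factory <- function(ntree = 50, mtry = NULL, seed = 1) {
  function(train, features) {
    set.seed(seed)
    lev <- sort(unique(as.character(train$label)))
    m <- if (is.null(mtry)) max(1L, floor(sqrt(length(features)))) else
      min(mtry, length(features))
    fit <- randomForest::randomForest(
      x = train[, features, drop = FALSE],
      y = label_factor(train$label, lev),
      ntree = ntree, mtry = m)
    structure(list(kind = "rf", fit = fit, features = features,
                   classes = lev),
              class = "window_classifier")
  }
}

loso_accuracy <- function(table, fit_fun, predict_fun) {
  folds <- loso_folds(table)
  acc <- vapply(folds, function(f) {
    train <- table[table$id %in% f$train, , drop = FALSE]
    test <- table[table$id == f$test, , drop = FALSE]
    fit <- fit_fun(train)
    mean(predict_fun(fit, test) == test$label)
  }, numeric(1))
  mean(acc)
}

#' Tune and train a random-forest window classifier
#'
#' Chooses \code{mtry} over the grid \code{1:min(10, D)} by mean
#' leave-one-subject-out overall accuracy, then fits the final forest on
#' all training individuals with the winning value. Deterministic under a
#' fixed seed.
#'
#' @param table Feature table with >= 2 individuals and >= 2 classes.
#' @param features Feature columns to use.
#' @param ntree Trees in the tuning and final forests (default 50; use 500
#'   for an initial exploration).
#' @param mtry_grid Candidate \code{mtry} values.
#' @param seed Integer seed.
#' @return A \code{window_classifier} with elements \code{fit},
#'   \code{mtry}, and \code{tuning} (accuracy per grid point).
#' @export
tune_and_train_rf <- function(table, features = feature_columns(table),
                              ntree = 50, mtry_grid = NULL, seed = 1) {
  check_classifier_input(table)
  D <- length(features)
  if (is.null(mtry_grid)) mtry_grid <- seq_len(min(10L, D))
  scores <- vapply(mtry_grid, function(m) {
    loso_accuracy(table,
                  function(train) {
                    set.seed(seed)
                    randomForest::randomForest(
                      x = train[, features, drop = FALSE],
                      y = label_factor(train$label,
                                       sort(unique(train$label))),
                      ntree = ntree, mtry = m)
                  },
                  function(fit, test)
                    as.character(predict(fit, test[, features, drop = FALSE])))
  }, numeric(1))
  best <- mtry_grid[which.max(scores)]
  set.seed(seed)
  lev <- sort(unique(as.character(table$label)))
  fit <- randomForest::randomForest(
    x = table[, features, drop = FALSE],
    y = label_factor(table$label, lev),
    ntree = ntree, mtry = best, importance = TRUE)
  structure(list(kind = "rf", fit = fit, features = features, classes = lev,
                 mtry = best,
                 tuning = data.frame(mtry = mtry_grid, accuracy = scores)),
            class = "window_classifier")
}

# Median-heuristic RBF bandwidth: 1 / median squared pairwise distance of
# (a subsample of) the standardized features.
median_gamma <- function(X, max_rows = 500L, seed = 1) {
  set.seed(seed)
  if (nrow(X) > max_rows) X <- X[sample.int(nrow(X), max_rows), , drop = FALSE]
  d2 <- as.numeric(stats::dist(X))^2
  med <- stats::median(d2[d2 > 0])
  if (!is.finite(med) || med <= 0) 1 else 1 / med
}

standardizer <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[sd == 0] <- 1
  list(mu = mu, sd = sd)
}

apply_standardizer <- function(X, sc) {
  sweep(sweep(X, 2L, sc$mu), 2L, sc$sd, "/")
}

#' Tune and train a radial-kernel SVM window classifier
#'
#' Grid search over the regularization grid \code{C = {0.25, 0.5, 1, 2, 4}}
#' crossed with a kernel-width grid (the median-heuristic gamma of the
#' training fold times \code{{0.5, 1, 2}}), maximizing mean
#' leave-one-subject-out overall accuracy. Features are standardized per
#' training fold (mean 0, sd 1) and test folds are transformed with the
#' training parameters only, so no information leaks from the held-out
#' individual.
#'
#' @inheritParams tune_and_train_rf
#' @param C_grid Regularization grid.
#' @param gamma_mult Multipliers on the median-heuristic gamma.
#' @return A \code{window_classifier} with the fitted SVM, its scaler, the
#'   chosen \code{C} and \code{gamma}, and the tuning table.
#' @export
tune_and_train_svm <- function(table, features = feature_columns(table),
                               C_grid = c(0.25, 0.5, 1, 2, 4),
                               gamma_mult = c(0.5, 1, 2), seed = 1) {
  check_classifier_input(table)
  grid <- expand.grid(C = C_grid, mult = gamma_mult)
  scores <- vapply(seq_len(nrow(grid)), function(g) {
    loso_accuracy(table,
      function(train) {
        Xtr <- as.matrix(train[, features, drop = FALSE])
        sc <- standardizer(Xtr)
        Xs <- apply_standardizer(Xtr, sc)
        g0 <- median_gamma(Xs, seed = seed)
        set.seed(seed)
        fit <- e1071::svm(x = Xs,
                          y = label_factor(train$label,
                                           sort(unique(train$label))),
                          kernel = "radial", cost = grid$C[g],
                          gamma = g0 * grid$mult[g], scale = FALSE)
        list(fit = fit, sc = sc)
      },
      function(fit, test) {
        Xte <- apply_standardizer(as.matrix(test[, features, drop = FALSE]),
                                  fit$sc)
        as.character(predict(fit$fit, Xte))
      })
  }, numeric(1))
  best <- which.max(scores)
  Xall <- as.matrix(table[, features, drop = FALSE])
  sc <- standardizer(Xall)
  Xs <- apply_standardizer(Xall, sc)
  g0 <- median_gamma(Xs, seed = seed)
  gamma <- g0 * grid$mult[best]
  set.seed(seed)
  lev <- sort(unique(as.character(table$label)))
  fit <- e1071::svm(x = Xs, y = label_factor(table$label, lev),
                    kernel = "radial", cost = grid$C[best], gamma = gamma,
                    scale = FALSE)
  structure(list(kind = "svm", fit = fit, features = features, classes = lev,
                 scaler = sc, C = grid$C[best], gamma = gamma,
                 tuning = cbind(grid, accuracy = scores)),
            class = "window_classifier")
}

# Untuned radial SVM (C = 1, median-heuristic gamma); used when a training
# fold holds a single individual and inner LOSO tuning is undefined.
default_svm <- function(table, features, seed = 1) {
  Xall <- as.matrix(table[, features, drop = FALSE])
  sc <- standardizer(Xall)
  Xs <- apply_standardizer(Xall, sc)
  g0 <- median_gamma(Xs, seed = seed)
  set.seed(seed)
  lev <- sort(unique(as.character(table$label)))
  fit <- e1071::svm(x = Xs, y = label_factor(table$label, lev),
                    kernel = "radial", cost = 1, gamma = g0, scale = FALSE)
  structure(list(kind = "svm", fit = fit, features = features, classes = lev,
                 scaler = sc, C = 1, gamma = g0, tuning = NULL),
            class = "window_classifier")
}

check_classifier_input <- function(table) {
  if (length(unique(table$id)) < 2L)
    stop("leave-one-subject-out tuning needs at least 2 individuals",
         call. = FALSE)
  if (length(unique(table$label)) < 2L)
    stop("need at least 2 classes", call. = FALSE)
  invisible(table)
}

#' Predict window labels with a trained baseline classifier
#'
#' Windows are predicted independently -- there is no serial dependence,
#' by design contrast with the hidden Markov model -- so shuffling window
#' order permutes the predictions identically.
#'
#' @param classifier A \code{window_classifier} from [tune_and_train_rf()],
#'   [tune_and_train_svm()] or an [rf_factory()] closure.
#' @param table Feature table carrying the classifier's features.
#' @return Character vector of predicted labels, one per row.
#' @export
predict_windows <- function(classifier, table) {
  miss <- setdiff(classifier$features, names(table))
  if (length(miss))
    stop("table lacks classifier feature(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  X <- table[, classifier$features, drop = FALSE]
  if (classifier$kind == "svm") {
    Xs <- apply_standardizer(as.matrix(X), classifier$scaler)
    as.character(predict(classifier$fit, Xs))
  } else {
    as.character(predict(classifier$fit, X))
  }
}

#' @export
print.window_classifier <- function(x, ...) {
  cat(sprintf("Window classifier (%s) over %d features\n",
              toupper(x$kind), length(x$features)))
  if (x$kind == "rf" && !is.null(x$mtry))
    cat(sprintf("  mtry = %d (LOSO-tuned)\n", x$mtry))
  if (x$kind == "svm")
    cat(sprintf("  C = %g, gamma = %.4g (LOSO-tuned)\n", x$C, x$gamma))
  invisible(x)
}
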