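# Leave-one-subject-out cross-validation driver and performance statistics:
# confusion matrices, per-class sensitivity / precision / one-vs-rest
# accuracy / F1, overall accuracy, Cohen's kappa.

#' Leave-one-subject-out folds
#'
#' One fold per individual: that individual is the whole test set and all
#' others are the training set, so an individual never occurs in training
#' and validation at the same time.
#'
#' @param table A feature table (or anything with an \code{id} column), or
#'   a character vector of individual ids.
#' @return A list of folds, each \code{list(train = ids, test = id)}.
#' @export
loso_folds <- function(table) {
  ids <- if (is.character(table)) unique(table) else
    unique(as.character(table$id))
  if (length(ids) < 2L)
    stop("leave-one-subject-out cross-validation needs at least 2 ",
         "individuals", call. = FALSE)
  lapply(ids, function(id) list(train = setdiff(ids, id), test = id))
}

#' Confusion matrix
#'
#' Counts \eqn{n_{ij}}: windows of true class \eqn{i} predicted as class
#' \eqn{j}. Classes absent from both vectors still appear as zero
#' rows/columns when listed in \code{classes}, so matrices from different
#' folds are conformable and can be summed.
#'
#' @param truth,pred Equal-length label vectors.
#' @param classes Fixed class order; default: sorted union of labels.
#' @return A K x K integer matrix of class \code{"confusion"} with
#'   dimnames \code{truth} x \code{predicted}.
#' @export
confusion <- function(truth, pred, classes = NULL) {
  if (length(truth) != length(pred))
    stop("truth and pred have different lengths", call. = FALSE)
  if (is.null(classes)) classes <- sort(union(unique(truth), unique(pred)))
  cm <- table(factor(as.character(truth), levels = classes),
              factor(as.character(pred), levels = classes))
  cm <- unclass(cm)
  names(dimnames(cm)) <- c("truth", "predicted")
  class(cm) <- c("confusion", class(cm))
  cm
}

#' Per-class performance metrics
#'
#' Sensitivity \eqn{Se_i = n_{ii} / \sum_j n_{ij}} (recall), precision
#' \eqn{Pr_i = n_{ii} / \sum_j n_{ji}} (positive predictive value),
#' one-vs-rest accuracy \eqn{Ac_i = (TP_i + TN_i) / N}, and
#' \eqn{F1_i = 2 Se_i Pr_i / (Se_i + Pr_i)}. Metrics with an empty
#' denominator (a class with no true or no predicted windows) are returned
#' as \code{NA} -- flagged missing, never silently 0 -- and should be
#' excluded from averages.
#'
#' @param cm A confusion matrix.
#' @return A data frame with columns \code{class, n, Se, Pr, Ac, F1}.
#' @export
class_metrics <- function(cm) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  tp <- diag(cm)
  rowS <- rowSums(cm)
  colS <- colSums(cm)
  Se <- ifelse(rowS > 0, tp / rowS, NA_real_)
  Pr <- ifelse(colS > 0, tp / colS, NA_real_)
  Ac <- (tp + (total - rowS - colS + tp)) / total
  F1 <- ifelse(!is.na(Se) & !is.na(Pr) & (Se + Pr) > 0,
               2 * Se * Pr / (Se + Pr), NA_real_)
  data.frame(class = rownames(cm), n = as.integer(rowS),
             Se = unname(Se), Pr = unname(Pr), Ac = unname(Ac),
             F1 = unname(F1), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Overall accuracy and Cohen's kappa
#'
#' Accuracy is \eqn{\mathrm{tr}(n) / N}. Cohen's kappa is
#' \eqn{(p_o - p_e) / (1 - p_e)} with expected agreement
#' \eqn{p_e = \sum_i r_i c_i / N^2} from the row and column margins;
#' \code{NA} (flagged undefined) when \eqn{p_e = 1}.
#'
#' @param cm A confusion matrix.
#' @return \code{list(accuracy =, kappa =)}.
#' @export
overall_metrics <- function(cm) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  kappa <- if (abs(1 - pe) < .Machine$double.eps^0.5) NA_real_ else
    (po - pe) / (1 - pe)
  list(accuracy = po, kappa = kappa)
}

#' @export
print.confusion <- function(x, ...) {
  cat("Confusion matrix (truth in rows, predictions in columns)\n")
  print(unclass(x))
  om <- overall_metrics(x)
  cat(sprintf("overall accuracy %.1f%%, kappa %.3f\n",
              100 * om$accuracy, om$kappa))
  invisible(x)
}

## ---- experiment driver ---------------------------------------------------

fit_predict_loso <- function(table, model, features, seed = 1,
                             hmm_args = list()) {
  folds <- loso_folds(table)
  preds <- rep(NA_character_, nrow(table))
  for (f in folds) {
    train <- table[table$id %in% f$train, , drop = FALSE]
    test_i <- which(table$id == f$test)
    test <- table[test_i, , drop = FALSE]
    # with a single training individual the inner leave-one-subject-out
    # tuning loop is undefined; fall back to the default hyperparameters
    tunable <- length(unique(train$id)) >= 2L
    p <- switch(model,
      rf = {
        fit <- if (tunable) tune_and_train_rf(train, features, seed = seed)
               else rf_factory(ntree = 50, seed = seed)(train, features)
        predict_windows(fit, test)
      },
      svm = {
        fit <- if (tunable) tune_and_train_svm(train, features, seed = seed)
               else default_svm(train, features, seed = seed)
        predict_windows(fit, test)
      },
      hmm = {
        fit <- do.call(behavior_hmm, c(list(train, features), hmm_args))
        predict(fit, test)$pred
      },
      stop("unknown model '", model, "'", call. = FALSE))
    preds[test_i] <- p
  }
  preds
}

#' Run the full model-by-window-size comparison
#'
#' For every window size, segments and featurises the labelled processed
#' traces; for every model, obtains pooled leave-one-subject-out
#' predictions (every individual is predicted by a model that never saw
#' it) and summarises them as a pooled confusion matrix with per-class and
#' overall metrics.
#'
#' @param processed A labelled \code{processed_trace} covering >= 2
#'   individuals.
#' @param window_sizes Window widths in seconds (default \code{c(2, 3, 5)}).
#' @param models Any of \code{"rf"}, \code{"svm"}, \code{"hmm"}.
#' @param features Feature names (default [preset_features_12()]); silently
#'   intersected with the available columns.
#' @param channels Channels passed to [window_features()].
#' @param purity,overlap Segmentation parameters.
#' @param seed Seed forwarded to the tuners.
#' @return An object of class \code{"experiment_report"}: list with
#'   \code{summary} (one row per model x window size: overall accuracy,
#'   kappa, n windows), \code{class_metrics} (long per-class table),
#'   \code{confusions} (named list of pooled confusion matrices) and
#'   \code{predictions}.
#' @export
run_experiment <- function(processed, window_sizes = c(2, 3, 5),
                           models = c("rf", "svm", "hmm"),
                           features = preset_features_12(),
                           channels = default_channels(),
                           purity = 1, overlap = 0, seed = 1) {
  models <- match.arg(models, c("rf", "svm", "hmm"), several.ok = TRUE)
  classes <- sort(setdiff(unique(processed$label), "unlabelled"))
  summaries <- list(); per_class <- list(); confusions <- list()
  predictions <- list()
  for (w in window_sizes) {
    tab <- window_features(processed, width_s = w, overlap = overlap,
                           purity = purity, channels = channels)
    feats <- intersect(features, feature_columns(tab))
    if (length(feats) < 2L)
      stop("fewer than 2 of the requested features are available",
           call. = FALSE)
    for (m in models) {
      key <- sprintf("%s_%gs", m, w)
      pred <- fit_predict_loso(tab, m, feats, seed = seed)
      cm <- confusion(tab$label, pred, classes)
      om <- overall_metrics(cm)
      cl <- class_metrics(cm)
      cl$model <- m; cl$window_s <- w
      summaries[[key]] <- data.frame(model = m, window_s = w,
                                     n_windows = nrow(tab),
                                     accuracy = om$accuracy,
                                     kappa = om$kappa,
                                     stringsAsFactors = FALSE)
      per_class[[key]] <- cl
      confusions[[key]] <- cm
      predictions[[key]] <- data.frame(id = tab$id,
                                       window_start = tab$window_start,
                                       label = tab$label, pred = pred,
                                       stringsAsFactors = FALSE)
    }
  }
  structure(list(summary = do.call(rbind, c(summaries,
                                            make.row.names = FALSE)),
                 class_metrics = do.call(rbind, c(per_class,
                                                  make.row.names = FALSE)),
                 confusions = confusions, predictions = predictions,
                 features = features, window_sizes = window_sizes,
                 models = models),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Model x window-size comparison (pooled leave-one-subject-out)\n\n")
  s <- x$summary
  s$accuracy <- sprintf("%.1f%%", 100 * s$accuracy)
  s$kappa <- sprintf("%.2f", s$kappa)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Per-class metric table in report (wide) shape
#'
#' One row per model and window size; per class, columns \code{Se}, \code{Pr}
#' and \code{Ac} in percent, then kappa and overall accuracy.
#'
#' @param report An \code{experiment_report}.
#' @return A wide data frame suitable for CSV export.
#' @export
report_table <- function(report) {
  cm <- report$class_metrics
  rows <- unique(cm[, c("model", "window_s")])
  out <- rows
  for (cl in unique(cm$class)) {
    for (met in c("Se", "Pr", "Ac")) {
      vals <- mapply(function(m, w) {
        v <- cm[cm$model == m & cm$window_s == w & cm$class == cl, met]
        if (length(v)) round(100 * v, 1) else NA_real_
      }, rows$model, rows$window_s)
      out[[paste(cl, met, sep = "_")]] <- as.numeric(vals)
    }
  }
  s <- report$summary
  out$kappa <- round(100 * s$kappa[match(paste(out$model, out$window_s),
                                         paste(s$model, s$window_s))], 1)
  out$overall_accuracy <- round(100 * s$accuracy[match(
    paste(out$model, out$window_s), paste(s$model, s$window_s))], 1)
  out
}

#' Barplot of per-class sensitivity by model
#'
#' @param x An \code{experiment_report}.
#' @param window_s Window size to plot (default: first).
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.experiment_report <- function(x, window_s = x$window_sizes[1L], ...) {
  cm <- x$class_metrics[x$class_metrics$window_s == window_s, ]
  mods <- unique(cm$model)
  classes <- unique(cm$class)
  M <- sapply(mods, function(m)
    cm$Se[cm$model == m][match(classes, cm$class[cm$model == m])])
  M <- matrix(as.numeric(M), nrow = length(classes),
              dimnames = list(classes, mods))
  graphics::barplot(t(M), beside = TRUE, ylim = c(0, 1),
                    legend.text = toupper(mods),
                    ylab = "sensitivity",
                    main = sprintf("%g-s windows", window_s), ...)
  invisible(x)
}
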