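# Window segmentation, time-domain summary statistics, correlation pruning,
# and greedy forward feature selection under leave-one-subject-out folds.

#' Segment a labelled trace into fixed windows
#'
#' Cuts each individual's trace into windows of \code{width_s} seconds,
#' stepping by \code{width_s * (1 - overlap)} (non-overlapping by default).
#' A window is retained iff at least \code{purity} of its samples share one
#' training-class label and that label is not \code{"unlabelled"}; the
#' window carries that label. With pure windows (the default) any bout
#' shorter than the window width can never fill a window and is dropped,
#' which is how sub-2-s behaviours disappear at 2-s segmentation.
#'
#' @param processed A labelled \code{processed_trace}.
#' @param width_s Window width in seconds (must cover >= 2 samples).
#' @param overlap Overlap fraction in \code{[0, 1)}.
#' @param purity Minimum fraction of samples sharing the window label.
#' @param rate_hz Sampling rate; defaults to the trace attribute.
#' @return A data frame of retained windows: \code{id}, \code{start_idx}
#'   (index into the individual's samples), \code{window_start} (s),
#'   \code{label}, plus attributes \code{n_per}, \code{step} (samples).
#' @export
segment_windows <- function(processed, width_s, overlap = 0, purity = 1,
                            rate_hz = NULL) {
  rate <- trace_rate(processed, rate_hz)
  if (overlap < 0 || overlap >= 1)
    stop("overlap must be in [0, 1)", call. = FALSE)
  if (purity <= 0 || purity > 1)
    stop("purity must be in (0, 1]", call. = FALSE)
  n_per <- as.integer(round(width_s * rate))
  if (n_per < 2L)
    stop("window width must cover at least 2 samples (width_s * rate >= 2)",
         call. = FALSE)
  step <- max(1L, as.integer(round(n_per * (1 - overlap))))
  parts <- lapply(unique(processed$id), function(id) {
    i <- which(processed$id == id)
    n <- length(i)
    if (n < n_per) return(NULL)
    starts <- seq.int(1L, n - n_per + 1L, by = step)
    lab <- processed$label[i]
    win_lab <- vapply(starts, function(s) {
      tb <- table(lab[s:(s + n_per - 1L)])
      top <- which.max(tb)
      if (names(tb)[top] != "unlabelled" && tb[top] / n_per >= purity)
        names(tb)[top] else NA_character_
    }, character(1))
    keep <- !is.na(win_lab)
    if (!any(keep)) return(NULL)
    data.frame(id = id, start_idx = starts[keep],
               window_start = processed$time_s[i][starts[keep]],
               label = win_lab[keep], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out))
    out <- data.frame(id = character(), start_idx = integer(),
                      window_start = numeric(), label = character(),
                      stringsAsFactors = FALSE)
  attr(out, "n_per") <- n_per
  attr(out, "step") <- step
  attr(out, "width_s") <- width_s
  out
}

.window_stats <- c("mean", "min", "max", "m", "IQR", "sd")

# Six summary statistics of a windows-in-columns matrix. Quantiles (median,
# IQR) use the linear-interpolation convention (R's default type 7).
window_stat_matrix <- function(M) {
  q <- apply(M, 2L, stats::quantile, probs = c(0.25, 0.5, 0.75), names = FALSE)
  rbind(mean = colMeans(M),
        min = apply(M, 2L, min),
        max = apply(M, 2L, max),
        m = q[2L, ],
        IQR = q[3L, ] - q[1L, ],
        sd = apply(M, 2L, stats::sd))
}

#' Default channel set for feature extraction
#'
#' Raw, static and dynamic axes plus roll: 10 channels, giving 60 candidate
#' features under the six summary statistics. Pitch and norm are available
#' channels but excluded by default (orientation-magnitude channels invite
#' overfitting once the collar correction has fixed the frame).
#' @return Character vector of channel names.
#' @export
default_channels <- function() {
  c("X", "Y", "Z", "sX", "sY", "sZ", "dX", "dY", "dZ", "roll")
}

#' Curated 12-feature set
#'
#' A compact feature set for collar accelerometry spanning posture (roll
#' median and spread, static surge and sway summaries) and gait (dynamic
#' surge and heave summaries): \code{m_roll, IQR_roll, mean_sX, sd_sX,
#' mean_dX, max_dX, m_Y, IQR_Y, min_sY, max_sY, sd_dZ, mean_dZ}. Usable as
#' a preset instead of data-driven correlation pruning.
#' @return Character vector of 12 feature names.
#' @export
preset_features_12 <- function() {
  c("m_roll", "IQR_roll", "mean_sX", "sd_sX", "mean_dX", "max_dX",
    "m_Y", "IQR_Y", "min_sY", "max_sY", "sd_dZ", "mean_dZ")
}

#' Extract per-window time-domain features
#'
#' For every retained window and every channel, computes the six summary
#' statistics mean, min, max, m (median), IQR (third minus first quartile,
#' linear-interpolation quantiles) and sd (sample, n-1 denominator).
#' Feature columns are named \code{<stat>_<channel>}, e.g. \code{m_roll}.
#' Angles are treated as plain numbers within a window.
#'
#' @param processed The labelled \code{processed_trace} the windows index.
#' @param windows Output of [segment_windows()].
#' @param channels Channel columns to summarise.
#' @return A feature table: \code{id}, \code{window_start}, \code{label},
#'   \code{seq_id} (contiguous-run identifier; a gap in retained windows or
#'   a change of individual starts a new sequence) and one numeric column
#'   per feature.
#' @export
extract_features <- function(processed, windows,
                             channels = default_channels()) {
  if (nrow(windows) == 0L) stop("no windows to extract features from",
                                call. = FALSE)
  miss <- setdiff(channels, names(processed))
  if (length(miss))
    stop("channels not present in processed trace: ",
         paste(miss, collapse = ", "), call. = FALSE)
  n_per <- attr(windows, "n_per")
  step <- attr(windows, "step")
  idx_by_id <- split(seq_len(nrow(processed)), processed$id)
  feat_blocks <- vector("list", length(channels))
  names(feat_blocks) <- channels
  abs_idx <- unlist(lapply(seq_len(nrow(windows)), function(w)
    idx_by_id[[windows$id[w]]][windows$start_idx[w]:(windows$start_idx[w] + n_per - 1L)]),
    use.names = FALSE)
  for (ch in channels) {
    M <- matrix(processed[[ch]][abs_idx], nrow = n_per)
    S <- window_stat_matrix(M)
    block <- t(S)
    colnames(block) <- paste0(rownames(S), "_", ch)
    feat_blocks[[ch]] <- block
  }
  feats <- do.call(cbind, feat_blocks)
  new_seq <- c(TRUE, windows$id[-1L] != windows$id[-nrow(windows)] |
                 diff(windows$start_idx) != step)
  out <- data.frame(id = windows$id, window_start = windows$window_start,
                    label = windows$label, seq_id = cumsum(new_seq),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(feats))
  rownames(out) <- NULL
  stopifnot(!anyNA(out))
  out
}

#' Segment and featurise in one step
#'
#' @inheritParams segment_windows
#' @inheritParams extract_features
#' @return A feature table, see [extract_features()].
#' @export
window_features <- function(processed, width_s, overlap = 0, purity = 1,
                            channels = default_channels(), rate_hz = NULL) {
  w <- segment_windows(processed, width_s, overlap, purity, rate_hz)
  extract_features(processed, w, channels)
}

feature_columns <- function(table) {
  setdiff(names(table), c("id", "window_start", "label", "seq_id", "pred"))
}

#' Greedy removal of highly correlated features
#'
#' Zero-variance features are dropped first (with a message). Then, while
#' any absolute pairwise Pearson correlation exceeds the threshold, the
#' member of the worst pair with the larger mean absolute correlation
#' against all remaining features is removed; ties are broken by dropping
#' the alphabetically later name, so the procedure is deterministic.
#'
#' @param table A feature table.
#' @param threshold Absolute-correlation threshold (default 0.9).
#' @return The table with offending feature columns removed; the drop order
#'   is recorded in attribute \code{"dropped"}.
#' @export
prune_correlated <- function(table, threshold = 0.9) {
  if (nrow(table) < 2L) stop("need at least 2 rows to compute correlations",
                             call. = FALSE)
  feats <- feature_columns(table)
  X <- as.matrix(table[, feats, drop = FALSE])
  dropped <- character(0)
  zv <- feats[apply(X, 2L, stats::sd) == 0]
  if (length(zv)) {
    message("dropping zero-variance feature(s): ", paste(zv, collapse = ", "))
    dropped <- c(dropped, zv)
    feats <- setdiff(feats, zv)
    X <- X[, feats, drop = FALSE]
  }
  while (length(feats) >= 2L) {
    C <- abs(stats::cor(X))
    diag(C) <- 0
    mx <- max(C)
    if (mx <= threshold) break
    hits <- which(C == mx, arr.ind = TRUE)
    pair <- sort(c(rownames(C)[hits[1L, 1L]], colnames(C)[hits[1L, 2L]]))
    mean_abs <- (rowSums(C) - 0) / (length(feats) - 1L)
    cand <- mean_abs[pair]
    drop <- if (cand[1L] > cand[2L]) pair[1L]
            else if (cand[2L] > cand[1L]) pair[2L]
            else max(pair)  # tie: alphabetically later name
    dropped <- c(dropped, drop)
    feats <- setdiff(feats, drop)
    X <- X[, feats, drop = FALSE]
  }
  out <- table[, c(setdiff(names(table), feature_columns(table)), feats)]
  attr(out, "dropped") <- dropped
  out
}

#' Forward feature selection under leave-one-subject-out folds
#'
#' Wrapper selection: every feature pair is evaluated first and the best
#' pair seeds the selection; single features are then added greedily while
#' the mean held-out overall accuracy strictly improves.
#'
#' @param table A feature table with >= 2 individuals.
#' @param model_factory Function \code{(train_table, features)} returning a
#'   fitted classifier accepted by [predict_windows()]. See
#'   [rf_factory()] for the default random-forest factory.
#' @param features Candidate features (default: all feature columns).
#' @param max_features Optional cap on the selection size.
#' @param verbose Print progress.
#' @return A list of class \code{"ffs"}: \code{features} (ordered
#'   selection) and \code{scores} (mean LOSO accuracy after each step;
#'   non-decreasing by construction).
#' @export
forward_feature_selection <- function(table, model_factory = rf_factory(),
                                      features = feature_columns(table),
                                      max_features = Inf, verbose = FALSE) {
  folds <- loso_folds(table)
  score_set <- function(fset) {
    acc <- vapply(folds, function(f) {
      train <- table[table$id %in% f$train, , drop = FALSE]
      test <- table[table$id == f$test, , drop = FALSE]
      fit <- model_factory(train, fset)
      mean(predict_windows(fit, test) == test$label)
    }, numeric(1))
    mean(acc)
  }
  if (length(features) < 2L)
    stop("need at least 2 candidate features", call. = FALSE)
  pairs <- utils::combn(sort(features), 2L, simplify = FALSE)
  pair_scores <- vapply(pairs, score_set, numeric(1))
  best <- which.max(pair_scores)
  selected <- pairs[[best]]
  scores <- pair_scores[best]
  if (verbose) message("pair: ", paste(selected, collapse = " + "),
                       " -> ", round(scores, 4))
  repeat {
    remaining <- setdiff(sort(features), selected)
    if (!length(remaining) || length(selected) >= max_features) break
    cand_scores <- vapply(remaining, function(f)
      score_set(c(selected, f)), numeric(1))
    b <- which.max(cand_scores)
    if (cand_scores[b] <= scores[length(scores)]) break
    selected <- c(selected, remaining[b])
    scores <- c(scores, cand_scores[b])
    if (verbose) message("+ ", remaining[b], " -> ",
                         round(cand_scores[b], 4))
  }
  structure(list(features = selected, scores = unname(scores)),
            class = "ffs")
}

#' @export
print.ffs <- function(x, ...) {
  cat("Forward feature selection:", length(x$features), "features\n")
  cat("  ", paste(x$features, collapse = ", "), "\n")
  cat("  held-out accuracy path:",
      paste(sprintf("%.3f", x$scores), collapse = " -> "), "\n")
  invisible(x)
}

#' Write a feature table with its provenance sidecar
#'
#' Serialises the table as CSV together with a JSON sidecar recording the
#' window specification, channel set and quantile convention.
#'
#' @param table Feature table.
#' @param path CSV path; the sidecar is \code{<path>.json}.
#' @param meta Extra fields to record (e.g. a selection trace).
#' @export
write_feature_table <- function(table, path, meta = list()) {
  utils::write.csv(table, path, row.names = FALSE)
  side <- c(list(features = feature_columns(table),
                 n_windows = nrow(table),
                 quantile_convention = "linear interpolation (R type 7)",
                 sd_convention = "sample (n-1)"),
            meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
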