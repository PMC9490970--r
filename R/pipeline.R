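# End-to-end pipeline: declarative YAML configuration, staged seeds, run
# manifest, and the simulate -> preprocess -> features -> train -> evaluate
# chain. A thin command-line wrapper over these functions ships in
# inst/scripts/collarHMM-pipeline.R.

#' Default run configuration
#'
#' A single declarative list validated against every stage's preconditions
#' before any computation. All randomness flows from \code{seed}, split
#' into fixed per-stage offsets.
#'
#' @return A named list of configuration values.
#' @export
default_config <- function() {
  list(
    seed = 1,
    n_individuals = 6,
    duration_s = 900,
    rate_hz = 10,
    bits = 8,
    range_g = 8,
    drift = "none",
    roll_offset_deg = 0,
    drift_sd_deg_per_min = 0,
    span_s = 5,
    collar_correction = FALSE,
    window_sizes = c(2, 3, 5),
    overlap = 0,
    purity = 1,
    channels = default_channels(),
    feature_preset = "preset_features_12",
    correlation_threshold = 0.9,
    models = c("rf", "svm", "hmm")
  )
}

#' Read a run configuration from YAML
#'
#' Unknown keys are a usage error (caught before any computation); missing
#' keys take their defaults.
#'
#' @param path YAML file path.
#' @return A validated configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(user)] <- user
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (cfg$n_individuals < 2)
    stop("config: n_individuals must be >= 2 for leave-one-subject-out ",
         "evaluation", call. = FALSE)
  if (cfg$duration_s <= 0) stop("config: duration_s must be > 0", call. = FALSE)
  if (cfg$span_s <= 0) stop("config: span_s must be > 0", call. = FALSE)
  for (w in cfg$window_sizes) {
    if (round(w * cfg$rate_hz) < 2)
      stop(sprintf(
        "config: window width %g s at %g Hz covers fewer than 2 samples; segmentation requires width * rate >= 2",
        w, cfg$rate_hz), call. = FALSE)
  }
  if (cfg$overlap < 0 || cfg$overlap >= 1)
    stop("config: overlap must be in [0, 1)", call. = FALSE)
  if (cfg$purity <= 0 || cfg$purity > 1)
    stop("config: purity must be in (0, 1]", call. = FALSE)
  if (!all(cfg$models %in% c("rf", "svm", "hmm")))
    stop("config: models must be among rf, svm, hmm", call. = FALSE)
  if (!cfg$feature_preset %in% c("preset_features_12", "pruned"))
    stop("config: feature_preset must be 'preset_features_12' or 'pruned'",
         call. = FALSE)
  cfg
}

stage_seed <- function(cfg, stage) {
  offsets <- c(simulate = 101L, preprocess = 211L, features = 307L,
               train = 401L, evaluate = 503L)
  as.integer(cfg$seed) + offsets[[stage]]
}

#' Run the full pipeline
#'
#' Simulates a dataset, preprocesses and annotates it, extracts features
#' per window size, trains and evaluates all configured models under
#' leave-one-subject-out cross-validation, and writes every artefact plus
#' a manifest (configuration, seeds, package version) under \code{outdir}.
#'
#' @param config A configuration list ([default_config()]), or the path of
#'   a YAML file for [read_run_config()].
#' @param outdir Output directory (created; existing files overwritten).
#' @param quiet Suppress progress messages.
#' @return The \code{experiment_report}, invisibly; artefacts on disk:
#'   \code{dataset/} (CSV dialects), \code{processed.csv},
#'   \code{processing_log.txt}, \code{features_<w>s.csv(+.json)},
#'   \code{report.csv}, \code{report.json}, \code{confusion_<cell>.csv},
#'   \code{manifest.json}.
#' @export
run_pipeline <- function(config = default_config(), outdir, quiet = FALSE) {
  cfg <- if (is.character(config)) read_run_config(config) else
    validate_config(utils::modifyList(default_config(), config))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)

  say("simulate: ", cfg$n_individuals, " individuals x ", cfg$duration_s, " s")
  sensor <- sensor_params(cfg$rate_hz, cfg$bits, cfg$range_g, cfg$drift,
                          cfg$roll_offset_deg, cfg$drift_sd_deg_per_min)
  ds <- simulate_dataset(cfg$n_individuals, cfg$duration_s,
                         sensor = sensor, seed = stage_seed(cfg, "simulate"))
  write_dataset(ds, file.path(outdir, "dataset"))

  say("preprocess: span ", cfg$span_s, " s",
      if (cfg$collar_correction) " + collar correction" else "")
  proc <- process_trace(ds$trace, span_s = cfg$span_s)
  if (cfg$collar_correction) {
    corr <- estimate_collar_offset(proc)
    corrected <- apply_rotation_correction(ds$trace, corr)
    attr(corrected, "rate_hz") <- cfg$rate_hz
    proc <- process_trace(corrected, span_s = cfg$span_s)
    alpha_deg <- vapply(corr$alpha, function(a) mean(a) * 180 / pi, numeric(1))
  } else {
    alpha_deg <- NULL
  }
  proc <- annotate_samples(proc, ds$annotations)
  utils::write.csv(as.data.frame(proc), file.path(outdir, "processed.csv"),
                   row.names = FALSE)
  log_lines <- c(
    sprintf("samples processed: %d", nrow(proc)),
    sprintf("degenerate zero-static samples: %d",
            attr(proc, "n_degenerate")),
    if (!is.null(alpha_deg))
      sprintf("estimated collar offset (deg): %s",
              paste(sprintf("%s=%.2f", names(alpha_deg), alpha_deg),
                    collapse = ", ")))
  writeLines(log_lines, file.path(outdir, "processing_log.txt"))

  features <- if (cfg$feature_preset == "preset_features_12")
    preset_features_12() else NULL
  for (w in cfg$window_sizes) {
    tab <- window_features(proc, w, cfg$overlap, cfg$purity, cfg$channels)
    if (is.null(features)) {
      pruned <- prune_correlated(tab, cfg$correlation_threshold)
      tab_out <- pruned
    } else tab_out <- tab
    write_feature_table(tab_out, file.path(outdir,
                                           sprintf("features_%gs.csv", w)),
                        meta = list(width_s = w, overlap = cfg$overlap,
                                    purity = cfg$purity,
                                    channels = cfg$channels,
                                    preset = cfg$feature_preset))
  }

  say("evaluate: ", paste(cfg$models, collapse = ", "), " x ",
      paste(cfg$window_sizes, collapse = "/"), " s windows")
  feats <- if (is.null(features)) {
    tab1 <- window_features(proc, cfg$window_sizes[1L], cfg$overlap,
                            cfg$purity, cfg$channels)
    feature_columns(prune_correlated(tab1, cfg$correlation_threshold))
  } else features
  report <- run_experiment(proc, cfg$window_sizes, cfg$models,
                           features = feats, channels = cfg$channels,
                           purity = cfg$purity, overlap = cfg$overlap,
                           seed = stage_seed(cfg, "train"))
  utils::write.csv(report_table(report), file.path(outdir, "report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(summary = report$summary, class_metrics = report$class_metrics),
    file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  for (key in names(report$confusions))
    utils::write.csv(as.data.frame(unclass(report$confusions[[key]])),
                     file.path(outdir, sprintf("confusion_%s.csv", key)))

  manifest <- list(
    package = "collarHMM",
    version = as.character(utils::packageVersion("collarHMM")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = cfg,
    stage_seeds = as.list(vapply(c("simulate", "preprocess", "features",
                                   "train", "evaluate"),
                                 function(s) stage_seed(cfg, s), integer(1)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: ", outdir)
  invisible(report)
}
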