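# Synthetic accelerometer data: behaviour schedules, signal synthesis,
# sensor quantization, and the CSV dialects used throughout the package.

#' Default ethogram for the synthetic-data generator
#'
#' Seven training-class behaviours of a grazing ungulate wearing a
#' neck-mounted accelerometer, with the statistical structure the analysis
#' pipeline assumes: a posture (head/neck pitch angle) determining the static
#' gravity vector, a behaviour-specific fore-aft oscillation (amplitude and
#' dominant frequency, kept at or below the 5 Hz motion band resolvable at
#' 10 Hz sampling), white sensor noise, an exponential mean bout (dwell)
#' duration, and a stationary occupancy weight. The weights are deliberately
#' imbalanced -- inactivity and grazing dominate, browsing high and trotting
#' are rare -- so that evaluation under natural class imbalance is exercised.
#'
#' The head angles of the two browsing classes are deliberately close
#' (separated by about 20 degrees before individual offsets): on a
#' neck-mounted sensor the neck-angle change between browsing low and high
#' is small, which is what makes those classes hard to separate.
#'
#' @return A data frame with one row per behaviour and columns
#'   \code{behavior}, \code{weight}, \code{mean_dwell_s},
#'   \code{head_angle_deg}, \code{dyn_amp_g}, \code{dyn_freq_hz},
#'   \code{noise_sd_g}.
#' @export
#' @examples
#' default_ethogram()
default_ethogram <- function() {
  data.frame(
    behavior      = c("grazing", "browsing_low", "browsing_high",
                      "inactivity", "walking", "trotting", "other"),
    weight        = c(0.30, 0.12, 0.05, 0.35, 0.10, 0.03, 0.05),
    mean_dwell_s  = c(40, 15, 12, 120, 20, 8, 10),
    head_angle_deg = c(-35, -8, 12, -5, 0, 3, -12),
    dyn_amp_g     = c(0.30, 0.25, 0.22, 0.04, 0.45, 0.75, 0.40),
    dyn_freq_hz   = c(1.5, 1.2, 1.1, 0.5, 1.8, 2.8, 2.0),
    noise_sd_g    = c(0.12, 0.12, 0.12, 0.04, 0.15, 0.18, 0.25),
    stringsAsFactors = FALSE
  )
}

validate_ethogram <- function(ethogram) {
  req <- c("behavior", "weight", "mean_dwell_s", "head_angle_deg",
           "dyn_amp_g", "dyn_freq_hz", "noise_sd_g")
  if (!is.data.frame(ethogram) || nrow(ethogram) == 0L)
    stop("ethogram must be a non-empty data frame", call. = FALSE)
  missing_cols <- setdiff(req, names(ethogram))
  if (length(missing_cols))
    stop("ethogram is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(ethogram$behavior))
    stop("duplicated behaviour labels in ethogram", call. = FALSE)
  if (any(ethogram$weight < 0) || sum(ethogram$weight) <= 0)
    stop("occupancy weights must be non-negative with a positive sum",
         call. = FALSE)
  if (any(ethogram$mean_dwell_s <= 0))
    stop("mean dwell times must be positive", call. = FALSE)
  if (any(ethogram$dyn_amp_g < 0) || any(ethogram$noise_sd_g < 0))
    stop("amplitudes and noise s.d. must be non-negative", call. = FALSE)
  if (any(ethogram$dyn_freq_hz < 0) || any(ethogram$dyn_freq_hz > 5))
    stop("oscillation frequencies must lie in [0, 5] Hz (the motion band ",
         "resolvable at 10 Hz sampling)", call. = FALSE)
  invisible(ethogram)
}

#' Sensor configuration
#'
#' Describes the logger: sampling rate, quantization depth, full-scale range,
#' and an optional collar-rotation model about the X (surge) axis. The
#' quantization step is \code{2 * range_g / (2^bits - 1)} g; samples are
#' rounded to the nearest grid point and saturate at \code{+/- range_g}.
#'
#' @param rate_hz Sampling rate in Hz.
#' @param bits ADC resolution in bits.
#' @param range_g Full-scale range in g (symmetric about zero).
#' @param drift Collar-rotation model: \code{"none"}, \code{"constant"}
#'   (a fixed roll offset of \code{roll_offset_deg}), or
#'   \code{"random_walk"} (a roll random walk with per-minute standard
#'   deviation \code{drift_sd_deg_per_min}, starting from
#'   \code{roll_offset_deg}).
#' @param roll_offset_deg Initial/constant roll offset of the collar, degrees.
#' @param drift_sd_deg_per_min Random-walk step scale, degrees per sqrt-minute.
#' @return An object of class \code{"sensor_params"}.
#' @export
sensor_params <- function(rate_hz = 10, bits = 8, range_g = 8,
                          drift = c("none", "constant", "random_walk"),
                          roll_offset_deg = 0, drift_sd_deg_per_min = 0) {
  drift <- match.arg(drift)
  if (rate_hz <= 0) stop("sampling rate must be positive", call. = FALSE)
  if (bits < 1 || range_g <= 0)
    stop("need bits >= 1 and range_g > 0", call. = FALSE)
  structure(list(rate_hz = rate_hz, bits = bits, range_g = range_g,
                 drift = drift, roll_offset_deg = roll_offset_deg,
                 drift_sd_deg_per_min = drift_sd_deg_per_min,
                 step_g = 2 * range_g / (2^bits - 1)),
            class = "sensor_params")
}

# Solve for the next-state sampling weights q of a strictly alternating
# semi-Markov schedule so that long-run time fractions match the occupancy
# weights. With next state j != i drawn with probability q_j / (1 - q_i),
# the embedded chain has stationary mass proportional to q_i (1 - q_i), so
# the time fraction of behaviour i is proportional to q_i (1 - q_i) m_i.
# Fixed-point iteration on q_i (1 - q_i) = c * w_i / m_i.
alternation_weights <- function(weight, mean_dwell) {
  r <- weight / mean_dwell
  r <- r / sum(r)
  q <- r
  for (iter in 1:200) {
    t <- r / pmax(1 - q, 0.05)
    q_new <- t / sum(t)
    if (max(abs(q_new - q)) < 1e-12) { q <- q_new; break }
    q <- q_new
  }
  q
}

#' Generate a Markovian behaviour schedule
#'
#' Produces alternating behaviour bouts with exponentially distributed dwell
#' times (memoryless bouts, so the per-window label process downstream is a
#' first-order Markov chain) whose long-run time-in-behaviour fractions
#' converge to the ethogram's occupancy weights.
#'
#' @param ethogram Ethogram data frame, see [default_ethogram()].
#' @param duration_s Schedule length in seconds (> 0).
#' @param seed Optional integer seed; identical inputs give identical output.
#' @return A data frame of intervals with columns \code{behavior},
#'   \code{start_s}, \code{stop_s}; intervals are ordered, non-overlapping
#'   and tile \code{[0, duration_s)}.
#' @export
make_behavior_schedule <- function(ethogram, duration_s, seed = NULL) {
  validate_ethogram(ethogram)
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0)
    stop("duration_s must be a positive number", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  B <- nrow(ethogram)
  w <- ethogram$weight / sum(ethogram$weight)
  m <- ethogram$mean_dwell_s
  if (B == 1L) {
    return(data.frame(behavior = ethogram$behavior, start_s = 0,
                      stop_s = duration_s, stringsAsFactors = FALSE))
  }
  q <- alternation_weights(w, m)
  # generous preallocation: expected bouts + 8 sd
  exp_bouts <- duration_s / sum(w * m) * 1.0
  n_max <- max(16L, ceiling(exp_bouts + 8 * sqrt(exp_bouts)) * 2L)
  lab <- integer(n_max); st <- numeric(n_max)
  cur <- sample.int(B, 1L, prob = w)
  t_now <- 0; k <- 0L
  while (t_now < duration_s) {
    k <- k + 1L
    if (k > length(lab)) { lab <- c(lab, integer(n_max)); st <- c(st, numeric(n_max)) }
    lab[k] <- cur
    st[k] <- t_now
    t_now <- t_now + stats::rexp(1L, rate = 1 / m[cur])
    p <- q; p[cur] <- 0
    cur <- sample.int(B, 1L, prob = p)
  }
  starts <- st[seq_len(k)]
  stops <- c(starts[-1L], duration_s)
  stops[k] <- duration_s
  data.frame(behavior = ethogram$behavior[lab[seq_len(k)]],
             start_s = starts, stop_s = pmin(stops, duration_s),
             stringsAsFactors = FALSE)
}

quantize_g <- function(x, sensor) {
  g <- round(x / sensor$step_g) * sensor$step_g
  pmin(pmax(g, -sensor$range_g), sensor$range_g)
}

#' Synthesize a raw accelerometer trace from a behaviour schedule
#'
#' Each behaviour contributes a static gravity vector set by its head/neck
#' pitch angle (unit magnitude 1 g), a sinusoidal dynamic component on the
#' surge (X) axis with a fixed per-behaviour phase, and white Gaussian noise
#' on all axes. Real gait signals are not constant sinusoids, so the
#' oscillation is modulated by a slowly varying log-normal AR(1) amplitude
#' envelope (\code{env_sd}, time constant \code{env_tau_s}) and its phase
#' performs a random walk (\code{phase_jitter} rad per sample), which
#' spreads the within-class distribution of window features the way
#' irregular locomotion does. An optional collar-rotation offset/drift
#' about X is applied to the assembled signal, which is then quantized to
#' the sensor grid.
#'
#' With a collar roll offset of \eqn{\delta}, the measured static vector has
#' roll \eqn{+\delta} under the \code{atan2(sY, sZ)} convention, so the
#' estimator in [estimate_collar_offset()] recovers the injected value.
#'
#' @param schedule Behaviour intervals from [make_behavior_schedule()].
#' @param ethogram Matching ethogram.
#' @param sensor A [sensor_params()] object.
#' @param seed Optional integer seed.
#' @param id Individual identifier stored with the trace.
#' @param env_sd Log-scale s.d. of the within-bout amplitude envelope
#'   (0 disables it, giving a pure sinusoid).
#' @param env_tau_s Time constant of the envelope AR(1) process, seconds.
#' @param phase_jitter Phase random-walk step s.d., radians per sample
#'   (0 gives a strictly periodic oscillation).
#' @return A data frame (one row per sample) with columns \code{id},
#'   \code{time_s}, \code{X}, \code{Y}, \code{Z} (g), and attributes
#'   \code{rate_hz} and \code{sensor}.
#' @export
synthesize_trace <- function(schedule, ethogram, sensor = sensor_params(),
                             seed = NULL, id = "ind1", env_sd = 0.4,
                             env_tau_s = 2, phase_jitter = 0.15) {
  validate_ethogram(ethogram)
  if (!inherits(sensor, "sensor_params")) stop("sensor must come from sensor_params()",
                                               call. = FALSE)
  unknown <- setdiff(unique(schedule$behavior), ethogram$behavior)
  if (length(unknown))
    stop("schedule labels not present in ethogram: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  duration <- max(schedule$stop_s) - min(schedule$start_s)
  rate <- sensor$rate_hz
  n <- floor(duration * rate)
  t <- (seq_len(n) - 1L) / rate + min(schedule$start_s)
  row <- findInterval(t, schedule$start_s)
  b_idx <- match(schedule$behavior[row], ethogram$behavior)

  B <- nrow(ethogram)
  phase <- stats::runif(B, 0, 2 * pi)
  a_rad <- ethogram$head_angle_deg * pi / 180
  # static gravity vector for head angle a: (-sin a, 0, cos a), so that the
  # derived pitch -atan(sX / sqrt(sY^2 + sZ^2)) equals a
  sx <- -sin(a_rad)[b_idx]
  sy <- rep(0, n)
  sz <- cos(a_rad)[b_idx]
  envelope <- if (env_sd > 0) {
    rho <- exp(-1 / (env_tau_s * rate))
    e <- stats::filter(stats::rnorm(n, 0, env_sd * sqrt(1 - rho^2)),
                       rho, method = "recursive")
    exp(as.numeric(e) - env_sd^2 / 2)
  } else rep(1, n)
  ph <- 2 * pi * ethogram$dyn_freq_hz[b_idx] * t + phase[b_idx]
  if (phase_jitter > 0) ph <- ph + cumsum(stats::rnorm(n, 0, phase_jitter))
  dyn <- ethogram$dyn_amp_g[b_idx] * envelope * sin(ph)
  nsd <- ethogram$noise_sd_g[b_idx]
  X <- sx + dyn + stats::rnorm(n, 0, nsd)
  Y <- sy + stats::rnorm(n, 0, nsd)
  Z <- sz + stats::rnorm(n, 0, nsd)

  alpha <- collar_angle_series(sensor, n)
  if (!is.null(alpha)) {
    ca <- cos(alpha); sa <- sin(alpha)
    Yr <- ca * Y + sa * Z
    Zr <- -sa * Y + ca * Z
    Y <- Yr; Z <- Zr
  }

  out <- data.frame(id = id, time_s = t,
                    X = quantize_g(X, sensor),
                    Y = quantize_g(Y, sensor),
                    Z = quantize_g(Z, sensor),
                    stringsAsFactors = FALSE)
  attr(out, "rate_hz") <- rate
  attr(out, "sensor") <- sensor
  out
}

# Roll-angle series (radians) injected by the collar model; NULL when zero.
collar_angle_series <- function(sensor, n) {
  if (sensor$drift == "none" && sensor$roll_offset_deg == 0) return(NULL)
  off <- sensor$roll_offset_deg * pi / 180
  if (sensor$drift == "random_walk" && sensor$drift_sd_deg_per_min > 0) {
    step_sd <- sensor$drift_sd_deg_per_min * pi / 180 / sqrt(60 * sensor$rate_hz)
    off + cumsum(stats::rnorm(n, 0, step_sd))
  } else {
    rep(off, n)
  }
}

#' Simulate a multi-individual, behaviour-annotated dataset
#'
#' Generates one schedule and trace per individual. Between-individual
#' variation -- the reason leave-one-subject-out validation is hard -- is
#' modelled by perturbing each individual's head angles by Gaussian offsets
#' and scaling its dynamic amplitudes by a log-normal factor.
#'
#' @param n_individuals Number of individuals (>= 1).
#' @param duration_s Annotated duration per individual, seconds.
#' @param ethogram Ethogram; defaults to [default_ethogram()].
#' @param sensor Sensor model; defaults to [sensor_params()].
#' @param seed Integer root seed; all per-individual seeds derive from it.
#' @param ind_angle_sd_deg Between-individual s.d. of head-angle offsets.
#' @param ind_amp_cv Between-individual coefficient of variation of
#'   dynamic amplitudes (log-normal).
#' @return A list of class \code{"collar_dataset"} with elements
#'   \code{trace} (stacked traces), \code{annotations} (stacked interval
#'   labels with an \code{id} column) and \code{sensor}.
#' @export
simulate_dataset <- function(n_individuals = 6, duration_s = 900,
                             ethogram = default_ethogram(),
                             sensor = sensor_params(), seed = 1,
                             ind_angle_sd_deg = 8, ind_amp_cv = 0.35) {
  validate_ethogram(ethogram)
  if (n_individuals < 1) stop("need at least one individual", call. = FALSE)
  traces <- vector("list", n_individuals)
  anns <- vector("list", n_individuals)
  for (i in seq_len(n_individuals)) {
    id <- sprintf("ind%02d", i)
    set.seed(seed + 7919L * i)
    eth_i <- ethogram
    eth_i$head_angle_deg <- eth_i$head_angle_deg +
      stats::rnorm(nrow(eth_i), 0, ind_angle_sd_deg)
    if (ind_amp_cv > 0)
      eth_i$dyn_amp_g <- eth_i$dyn_amp_g *
        exp(stats::rnorm(nrow(eth_i), -ind_amp_cv^2 / 2, ind_amp_cv))
    sched <- make_behavior_schedule(eth_i, duration_s)
    tr <- synthesize_trace(sched, eth_i, sensor, id = id)
    sched$id <- id
    traces[[i]] <- tr
    anns[[i]] <- sched[, c("id", "behavior", "start_s", "stop_s")]
  }
  trace <- do.call(rbind, traces)
  attr(trace, "rate_hz") <- sensor$rate_hz
  structure(list(trace = trace,
                 annotations = do.call(rbind, anns),
                 sensor = sensor),
            class = "collar_dataset")
}

#' @export
print.collar_dataset <- function(x, ...) {
  ids <- unique(x$trace$id)
  cat("Synthetic collar-accelerometer dataset\n")
  cat(sprintf("  individuals : %d (%s%s)\n", length(ids),
              paste(utils::head(ids, 3), collapse = ", "),
              if (length(ids) > 3) ", ..." else ""))
  cat(sprintf("  samples     : %d at %g Hz\n", nrow(x$trace),
              x$sensor$rate_hz))
  cat(sprintf("  behaviours  : %s\n",
              paste(sort(unique(x$annotations$behavior)), collapse = ", ")))
  invisible(x)
}

## ---- CSV dialects --------------------------------------------------------

.trace_epoch <- function() as.POSIXct("2020-03-01 06:00:00", tz = "UTC")

#' Write / read accelerometer CSV
#'
#' Logger-style CSV with header \code{tag_id,datetime,accX,accY,accZ};
#' datetime is ISO-8601 with fractional seconds, acceleration in g.
#' Reading validates that timestamps are strictly increasing per tag and
#' reports the offending line number otherwise.
#'
#' @param trace Trace data frame (\code{id,time_s,X,Y,Z}).
#' @param path File path.
#' @return \code{write_accel_csv} returns \code{path} invisibly;
#'   \code{read_accel_csv} returns a trace data frame with attribute
#'   \code{rate_hz} inferred from the timestamps.
#' @export
write_accel_csv <- function(trace, path) {
  t0 <- .trace_epoch()
  dt <- format(t0 + trace$time_s, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")
  out <- data.frame(tag_id = trace$id, datetime = dt,
                    accX = trace$X, accY = trace$Y, accZ = trace$Z)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_accel_csv
#' @export
read_accel_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("tag_id", "datetime", "accX", "accY", "accZ")
  if (!all(req %in% names(raw)))
    stop("malformed accelerometer CSV (line 1): expected header ",
         paste(req, collapse = ","), call. = FALSE)
  dt <- as.POSIXct(raw$datetime, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  if (anyNA(dt)) {
    bad <- which(is.na(dt))[1L]
    stop(sprintf("malformed accelerometer CSV (line %d): unparseable datetime '%s'",
                 bad + 1L, raw$datetime[bad]), call. = FALSE)
  }
  secs <- as.numeric(dt) - as.numeric(dt[1L])
  for (tag in unique(raw$tag_id)) {
    i <- which(raw$tag_id == tag)
    d <- diff(secs[i])
    if (any(d <= 0)) {
      bad <- i[which(d <= 0)[1L] + 1L]
      stop(sprintf("malformed accelerometer CSV (line %d): non-monotone timestamp for tag '%s'",
                   bad + 1L, tag), call. = FALSE)
    }
  }
  out <- data.frame(id = raw$tag_id, time_s = secs,
                    X = raw$accX, Y = raw$accY, Z = raw$accZ,
                    stringsAsFactors = FALSE)
  # re-base each tag's clock to its own first sample
  out$time_s <- out$time_s - stats::ave(out$time_s, out$id, FUN = min)
  dtt <- diff(out$time_s)
  dtt <- dtt[dtt > 0]
  attr(out, "rate_hz") <- if (length(dtt)) 1 / stats::median(dtt) else NA_real_
  out
}

#' Write / read behaviour-annotation CSV
#'
#' Event-logger style export with header \code{subject,behavior,start_s,stop_s}.
#' An empty file (header only) reads back as an empty annotation set.
#'
#' @param annotations Data frame with \code{id,behavior,start_s,stop_s}.
#' @param path File path.
#' @export
write_annotations_csv <- function(annotations, path) {
  out <- data.frame(subject = annotations$id, behavior = annotations$behavior,
                    start_s = annotations$start_s, stop_s = annotations$stop_s)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotations_csv
#' @export
read_annotations_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject", "behavior", "start_s", "stop_s")
  if (!all(req %in% names(raw)))
    stop("malformed annotation CSV (line 1): expected header ",
         paste(req, collapse = ","), call. = FALSE)
  if (nrow(raw) == 0L)
    return(data.frame(id = character(), behavior = character(),
                      start_s = numeric(), stop_s = numeric(),
                      stringsAsFactors = FALSE))
  bad <- which(raw$stop_s <= raw$start_s)
  if (length(bad))
    stop(sprintf("malformed annotation CSV (line %d): stop_s <= start_s",
                 bad[1L] + 1L), call. = FALSE)
  data.frame(id = raw$subject, behavior = raw$behavior,
             start_s = raw$start_s, stop_s = raw$stop_s,
             stringsAsFactors = FALSE)
}

#' Write / read a dataset directory
#'
#' A dataset directory holds \code{acceleration.csv}, \code{annotations.csv}
#' and \code{sensor.json} (rate, bits, range, drift model).
#'
#' @param dataset A \code{collar_dataset} (or list with \code{trace},
#'   \code{annotations}, optionally \code{sensor}).
#' @param dir Directory path (created if absent).
#' @return \code{write_dataset} returns the file paths invisibly;
#'   \code{read_dataset} returns a \code{collar_dataset}.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(acceleration = file.path(dir, "acceleration.csv"),
             annotations = file.path(dir, "annotations.csv"),
             sensor = file.path(dir, "sensor.json"))
  write_accel_csv(dataset$trace, paths[["acceleration"]])
  write_annotations_csv(dataset$annotations, paths[["annotations"]])
  sensor <- dataset$sensor
  if (is.null(sensor)) sensor <- sensor_params(attr(dataset$trace, "rate_hz"))
  jsonlite::write_json(unclass(sensor), paths[["sensor"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  trace <- read_accel_csv(file.path(dir, "acceleration.csv"))
  annotations <- read_annotations_csv(file.path(dir, "annotations.csv"))
  sensor_path <- file.path(dir, "sensor.json")
  sensor <- NULL
  if (file.exists(sensor_path)) {
    s <- jsonlite::read_json(sensor_path, simplifyVector = TRUE)
    sensor <- sensor_params(s$rate_hz, s$bits, s$range_g, s$drift,
                            s$roll_offset_deg, s$drift_sd_deg_per_min)
    attr(trace, "rate_hz") <- sensor$rate_hz
  }
  structure(list(trace = trace, annotations = annotations, sensor = sensor),
            class = "collar_dataset")
}
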