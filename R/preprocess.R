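# Signal decomposition (static/dynamic), Euler angles, l2-norm,
# collar-rotation correction, and sample-level behaviour annotation.

# Centred running mean with shrinking windows at the edges: interior samples
# average over k points (k odd), the first and last (k-1)/2 samples average
# over whatever part of the window exists.
running_mean <- function(x, k) {
  n <- length(x)
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

trace_rate <- function(trace, rate_hz = NULL) {
  r <- if (!is.null(rate_hz)) rate_hz else attr(trace, "rate_hz")
  if (is.null(r) || !is.finite(r) || r <= 0)
    stop("sampling rate unknown: pass rate_hz or use a trace carrying a ",
         "'rate_hz' attribute", call. = FALSE)
  r
}

#' Static (gravitational) acceleration by centred running mean
#'
#' Smooths each raw axis with a centred running mean whose support is the
#' nearest odd number of samples to the requested span:
#' \code{k = 2 * floor(span_s * rate / 2) + 1}, i.e. 51 samples for a 5-s
#' span at 10 Hz. Edges use the shrinking (partial) window so no samples
#' are dropped.
#'
#' @param trace Trace data frame with columns \code{X,Y,Z}.
#' @param span_s Smoother span in seconds (> 0).
#' @param rate_hz Sampling rate; taken from the trace attribute if missing.
#' @return A data frame with columns \code{sX,sY,sZ}.
#' @seealso [static_support()] for the interior window length in samples.
#' @export
estimate_static <- function(trace, span_s = 5, rate_hz = NULL) {
  rate <- trace_rate(trace, rate_hz)
  if (span_s <= 0) stop("span_s must be positive", call. = FALSE)
  k <- static_support(span_s, rate)
  if (k < 1) stop("span_s * rate must cover at least one sample", call. = FALSE)
  data.frame(sX = running_mean(trace$X, k),
             sY = running_mean(trace$Y, k),
             sZ = running_mean(trace$Z, k))
}

#' @rdname estimate_static
#' @param span_s,rate_hz Span (s) and sampling rate (Hz).
#' @export
static_support <- function(span_s, rate_hz) {
  2L * as.integer(floor(span_s * rate_hz / 2)) + 1L
}

#' Dynamic acceleration
#'
#' Per-sample absolute deviation of the raw signal from the static
#' component, \code{dX = |X - sX|} (likewise Y, Z); non-negative by
#' construction.
#'
#' @param trace Trace with \code{X,Y,Z}.
#' @param static Static channels from [estimate_static()].
#' @return Data frame with \code{dX,dY,dZ}.
#' @export
compute_dynamic <- function(trace, static) {
  if (nrow(trace) != nrow(static))
    stop("trace and static channels have different lengths", call. = FALSE)
  data.frame(dX = abs(trace$X - static$sX),
             dY = abs(trace$Y - static$sY),
             dZ = abs(trace$Z - static$sZ))
}

#' Euler angles from the static vector
#'
#' Roll is rotation about the X (surge) axis, \code{atan2(sY, sZ)}, in
#' \eqn{(-\pi, \pi]}; pitch is rotation about the Y (sway) axis,
#' \code{-atan(sX / sqrt(sY^2 + sZ^2))}, in \eqn{[-\pi/2, \pi/2]}, taking
#' the limiting value \eqn{\mp\pi/2} when \code{sY = sZ = 0} with
#' \code{sX} nonzero. An all-zero static vector yields roll 0 and pitch 0
#' (callers count these degenerate samples).
#'
#' @param sX,sY,sZ Static channels.
#' @return Numeric vector of angles in radians.
#' @export
compute_roll <- function(sY, sZ) {
  atan2(sY, sZ)
}

#' @rdname compute_roll
#' @export
compute_pitch <- function(sX, sY, sZ) {
  den <- sqrt(sY^2 + sZ^2)
  out <- -atan(ifelse(den > 0, sX / den, 0))
  lim <- den == 0 & sX != 0
  out[lim] <- -sign(sX[lim]) * pi / 2
  out
}

#' Euclidean norm of the raw axes
#'
#' Orientation-independent acceleration magnitude
#' \code{sqrt(X^2 + Y^2 + Z^2)}; invariant under any rotation of the axes.
#'
#' @param trace Trace with \code{X,Y,Z}.
#' @return Numeric vector in g.
#' @export
compute_norm <- function(trace) {
  sqrt(trace$X^2 + trace$Y^2 + trace$Z^2)
}

#' Full per-sample processing of a raw trace
#'
#' Runs the static/dynamic decomposition, roll, pitch and norm for every
#' individual in the trace. Degenerate all-zero static vectors are counted
#' in the \code{"n_degenerate"} attribute (their angles are set to 0).
#'
#' @inheritParams estimate_static
#' @return A \code{processed_trace} data frame: the input columns plus
#'   \code{sX,sY,sZ,dX,dY,dZ,roll,pitch,norm} and a \code{label} column
#'   (initially \code{"unlabelled"}; see [annotate_samples()]).
#' @export
process_trace <- function(trace, span_s = 5, rate_hz = NULL) {
  rate <- trace_rate(trace, rate_hz)
  parts <- lapply(split(seq_len(nrow(trace)), trace$id), function(i) {
    tr <- trace[i, , drop = FALSE]
    st <- estimate_static(tr, span_s, rate)
    dy <- compute_dynamic(tr, st)
    out <- cbind(tr, st, dy)
    out$roll <- compute_roll(st$sY, st$sZ)
    out$pitch <- compute_pitch(st$sX, st$sY, st$sZ)
    out$norm <- compute_norm(tr)
    out
  })
  out <- do.call(rbind, parts[unique(trace$id)])
  rownames(out) <- NULL
  out$label <- "unlabelled"
  degen <- out$sX == 0 & out$sY == 0 & out$sZ == 0
  out$roll[degen] <- 0
  out$pitch[degen] <- 0
  attr(out, "rate_hz") <- rate
  attr(out, "span_s") <- span_s
  attr(out, "n_degenerate") <- sum(degen)
  class(out) <- c("processed_trace", "data.frame")
  out
}

## ---- collar rotation -----------------------------------------------------

#' Rotation matrix about the X axis
#'
#' \deqn{R_x(\phi) = \begin{pmatrix} 1 & 0 & 0 \\ 0 & \cos\phi & -\sin\phi
#'   \\ 0 & \sin\phi & \cos\phi \end{pmatrix}}
#'
#' @param phi Angle in radians.
#' @return A 3x3 rotation matrix (determinant 1).
#' @export
rot_x <- function(phi) {
  matrix(c(1, 0, 0,
           0, cos(phi), sin(phi),
           0, -sin(phi), cos(phi)), nrow = 3)
}

wrap_angle <- function(x) {
  w <- ((x + pi) %% (2 * pi)) - pi
  w[w == -pi] <- pi
  w
}

# Circular median of angles: rotate by the circular mean, take the linear
# median of wrapped residuals, rotate back. Robust to activity bursts and
# cheap enough for long windows.
circ_median <- function(theta) {
  mu <- atan2(mean(sin(theta)), mean(cos(theta)))
  wrap_angle(mu + stats::median(wrap_angle(theta - mu)))
}

#' Estimate the collar-rotation offset from the roll series
#'
#' The offset \eqn{\alpha} of a neck collar that has rotated about the
#' animal's surge axis appears as a shift of the roll angle away from its
#' reference value (0 when the sensor hangs in its nominal position). It is
#' estimated as the circular median of roll minus \code{reference_roll}:
#' the median resists short activity bursts that perturb the static vector.
#' With \code{window_s = NULL} a single constant offset per individual is
#' returned; otherwise block-wise circular medians over windows of the
#' given length are interpolated into a slowly-varying per-sample series.
#'
#' @param processed A \code{processed_trace} (single individual, or the
#'   estimate is computed per individual).
#' @param window_s Estimation window in seconds, or \code{NULL} for one
#'   constant offset over the whole trace. Must cover at least 3 samples
#'   and be no shorter than the static-smoother span.
#' @param reference_roll Reference roll in radians (default 0).
#' @return An object of class \code{"collar_correction"}: a list with
#'   \code{alpha} (radians; scalar per individual or per-sample vector),
#'   \code{window_s} and \code{reference_roll}.
#' @export
estimate_collar_offset <- function(processed, window_s = NULL,
                                   reference_roll = 0) {
  rate <- trace_rate(processed)
  span <- attr(processed, "span_s")
  if (!is.null(window_s)) {
    if (window_s * rate < 3)
      stop("estimation window must cover at least 3 samples", call. = FALSE)
    if (!is.null(span) && window_s < span)
      stop("estimation window must be at least the static-smoother span",
           call. = FALSE)
  }
  per_id <- lapply(split(processed$roll, processed$id), function(roll) {
    if (is.null(window_s)) {
      wrap_angle(circ_median(roll) - reference_roll)
    } else {
      n <- length(roll)
      w <- max(3L, as.integer(round(window_s * rate)))
      starts <- seq(1L, n, by = w)
      centers <- pmin(starts + (w - 1L) / 2, n)
      vals <- vapply(starts, function(s)
        circ_median(roll[s:min(s + w - 1L, n)]), numeric(1))
      if (length(vals) == 1L) {
        rep(wrap_angle(vals - reference_roll), n)
      } else {
        # unwrap block medians before interpolating so the series varies
        # smoothly even near +/- pi
        d <- wrap_angle(diff(vals))
        unwrapped <- vals[1L] + c(0, cumsum(d))
        a <- stats::approx(centers, unwrapped, xout = seq_len(n),
                           rule = 2)$y
        wrap_angle(a - reference_roll)
      }
    }
  })
  ids <- unique(processed$id)
  structure(list(alpha = per_id[ids], window_s = window_s,
                 reference_roll = reference_roll),
            class = "collar_correction")
}

#' Apply the collar-rotation correction to the raw axes
#'
#' Rotates the measured axes about X so that a static vector observed with
#' roll \eqn{\alpha} is brought back to the reference roll:
#' \code{Yc = cos(a) Y - sin(a) Z}, \code{Zc = sin(a) Y + cos(a) Z} (i.e.
#' multiplication by [rot_x()] of the estimated offset), leaving X and the
#' per-sample norm untouched.
#'
#' @param trace A trace or processed trace with \code{X,Y,Z}.
#' @param correction A \code{collar_correction}, or a numeric offset in
#'   radians (recycled per individual).
#' @return The trace with \code{Y} and \code{Z} replaced by the corrected
#'   axes (columns keep their names so the result can be re-processed).
#' @export
apply_rotation_correction <- function(trace, correction) {
  alpha_for <- function(id, n) {
    if (inherits(correction, "collar_correction")) {
      a <- correction$alpha[[id]]
      if (is.null(a)) stop("no collar correction for individual '", id, "'",
                           call. = FALSE)
      if (length(a) == 1L) rep(a, n) else a
    } else {
      rep(correction, length.out = n)
    }
  }
  out <- trace
  for (id in unique(trace$id)) {
    i <- which(trace$id == id)
    a <- alpha_for(id, length(i))
    if (length(a) != length(i))
      stop("per-sample correction length mismatch for '", id, "'",
           call. = FALSE)
    if (any(!is.finite(a))) stop("collar offset must be finite", call. = FALSE)
    ca <- cos(a); sa <- sin(a)
    Y <- trace$Y[i]; Z <- trace$Z[i]
    out$Y[i] <- ca * Y - sa * Z
    out$Z[i] <- sa * Y + ca * Z
  }
  out
}

## ---- annotation ----------------------------------------------------------

#' Ethogram-to-training-class map
#'
#' Maps the raw annotation categories of the reindeer ethogram onto the 7
#' classes used for model training: the grazing variants merge into
#' \code{grazing}; resting, sleeping, ruminating and standing merge into
#' \code{inactivity}; running merges into \code{trotting}; grooming,
#' digging, agonistic behaviour, head scratching and undefined events
#' merge into \code{other}; \code{missing data} maps to \code{NA} and is
#' excluded from training entirely. The 7 training-class names map to
#' themselves so already-merged labels pass through.
#'
#' @return A named character vector (raw label -> training class).
#' @export
ethogram_class_map <- function() {
  raw <- c(
    "grazing"                      = "grazing",
    "grazing from a hole"          = "grazing",
    "grazing while walking"        = "grazing",
    "browsing high"                = "browsing_high",
    "browsing low"                 = "browsing_low",
    "resting"                      = "inactivity",
    "sleeping"                     = "inactivity",
    "ruminating"                   = "inactivity",
    "standing"                     = "inactivity",
    "grooming"                     = "other",
    "walking"                      = "walking",
    "trotting"                     = "trotting",
    "running"                      = "trotting",
    "digging"                      = "other",
    "agonistic behaviour"          = "other",
    "scratching head against tree" = "other",
    "other"                        = "other",
    "missing data"                 = NA_character_
  )
  classes <- setdiff(unique(raw), NA_character_)
  c(raw, stats::setNames(classes, classes))
}

#' Training classes of the shipped ethogram map
#' @return Character vector of the 7 training-class names.
#' @export
training_classes <- function() {
  sort(setdiff(unique(ethogram_class_map()), NA_character_))
}

#' Attach behaviour labels to samples
#'
#' Every sample falling inside an annotation interval \code{[start, stop)}
#' of its individual receives that interval's label mapped through
#' \code{class_map}; samples outside all intervals, and samples whose raw
#' label maps to \code{NA} (missing data), are \code{"unlabelled"}.
#'
#' @param processed A \code{processed_trace}.
#' @param annotations Data frame \code{id,behavior,start_s,stop_s}.
#' @param class_map Named character vector; defaults to
#'   [ethogram_class_map()].
#' @return The processed trace with its \code{label} column filled in.
#' @export
annotate_samples <- function(processed, annotations,
                             class_map = ethogram_class_map()) {
  key <- tolower(trimws(annotations$behavior))
  unknown <- setdiff(unique(key), names(class_map))
  if (length(unknown))
    stop("unknown ethogram label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  mapped <- unname(class_map[key])
  out <- processed
  out$label <- "unlabelled"
  for (id in unique(annotations$id)) {
    ai <- which(annotations$id == id)
    ti <- which(processed$id == id)
    if (!length(ti)) next
    ord <- ai[order(annotations$start_s[ai])]
    t <- processed$time_s[ti]
    row <- findInterval(t, annotations$start_s[ord])
    lab <- rep(NA_character_, length(t))
    inside <- row >= 1L
    hit <- ord[row[inside]]
    ok <- t[inside] < annotations$stop_s[hit]
    lab[inside][ok] <- mapped[hit][ok]
    lab[is.na(lab)] <- "unlabelled"
    out$label[ti] <- lab
  }
  out
}
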