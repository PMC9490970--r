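# Static/dynamic decomposition, Euler angles, norm, collar correction,
# and sample annotation.

test_that("the 5-s smoother at 10 Hz has a 51-sample impulse response", {
  n <- 201
  tr <- constant_trace(n, X = 0, Y = 0, Z = 0)
  tr$X[101] <- 1
  st <- estimate_static(tr, span_s = 5)
  nz <- which(st$sX != 0)
  expect_equal(length(nz), 51L)
  expect_equal(nz, 76:126)
  expect_equal(unique(st$sX[nz]), 1 / 51)
  expect_equal(static_support(5, 10), 51L)
})

test_that("the smoother is exact on constants and uses shrinking edges", {
  tr <- constant_trace(120, X = 0.25, Y = -0.5, Z = 1)
  st <- estimate_static(tr, span_s = 5)
  expect_equal(st$sX, rep(0.25, 120))
  expect_equal(st$sY, rep(-0.5, 120))
  expect_equal(st$sZ, rep(1, 120))
  # shrinking edge: first sample averages the first 26 samples
  tr2 <- constant_trace(60, X = 0)
  tr2$X <- seq_len(60)
  st2 <- estimate_static(tr2, span_s = 5)
  expect_equal(st2$sX[1], mean(1:26))
  expect_equal(st2$sX[60], mean(35:60))
  expect_equal(st2$sX[30], mean(5:55))
})

test_that("a 5 Hz square wave averages to +/- 1/51 at interior samples", {
  n <- 200
  tr <- constant_trace(n)
  tr$X <- rep(c(1, -1), n / 2)
  st <- estimate_static(tr, span_s = 5)
  interior <- 26:(n - 25)
  # 51-sample window holds 26 of one sign and 25 of the other
  expect_true(all(abs(abs(st$sX[interior]) - 1 / 51) < 1e-12))
})

test_that("estimate_static validates span and rate", {
  tr <- constant_trace(50)
  expect_error(estimate_static(tr, span_s = 0), "positive")
  expect_error(estimate_static(tr, span_s = -1), "positive")
  tr2 <- constant_trace(50); attr(tr2, "rate_hz") <- NULL
  expect_error(estimate_static(tr2), "rate")
})

test_that("dynamic acceleration is the absolute residual", {
  tr <- constant_trace(5, X = 0.5)
  st <- data.frame(sX = rep(-0.25, 5), sY = rep(0, 5), sZ = rep(1, 5))
  dy <- compute_dynamic(tr, st)
  expect_equal(dy$dX, rep(0.75, 5))
  expect_equal(dy$dZ, rep(0, 5))
  expect_error(compute_dynamic(tr, st[1:3, ]), "length")
  set.seed(1)
  tr$X <- rnorm(5); st$sX <- rnorm(5)
  expect_true(all(compute_dynamic(tr, st)$dX >= 0))
})

test_that("roll and pitch follow the stated angle conventions", {
  expect_equal(compute_roll(0, 1), 0)
  expect_equal(compute_pitch(0, 0, 1), 0)
  expect_equal(abs(compute_roll(0, -1)), pi)          # 180 degrees
  expect_equal(compute_pitch(-1, 0, 0), pi / 2)       # +90 degrees
  expect_equal(compute_pitch(1, 0, 0), -pi / 2)
  expect_equal(compute_roll(1, 0), pi / 2)
  # ranges over random static vectors
  set.seed(2)
  s <- matrix(rnorm(300), ncol = 3)
  r <- compute_roll(s[, 2], s[, 3])
  p <- compute_pitch(s[, 1], s[, 2], s[, 3])
  expect_true(all(r > -pi & r <= pi))
  expect_true(all(abs(p) <= pi / 2))
})

test_that("the decomposition reconstructs the raw signal exactly", {
  ds <- simulate_dataset(1, 60, seed = 8)
  pr <- process_trace(ds$trace)
  resid <- ds$trace$X - pr$sX
  expect_equal(pr$sX + resid, ds$trace$X)
  expect_equal(pr$dX, abs(resid))
  expect_equal(nrow(pr), nrow(ds$trace))   # processing never drops samples
  expect_equal(pr$norm, sqrt(ds$trace$X^2 + ds$trace$Y^2 + ds$trace$Z^2))
})

test_that("norm is the Euclidean magnitude and rotation-invariant", {
  tr <- constant_trace(1, X = 3, Y = 4, Z = 0)
  expect_equal(compute_norm(tr), 5)
  expect_equal(compute_norm(constant_trace(1, X = 0, Y = 0, Z = 0)), 0)
  set.seed(3)
  tr <- constant_trace(100)
  tr$X <- rnorm(100); tr$Y <- rnorm(100); tr$Z <- rnorm(100)
  rot <- apply_rotation_correction(tr, 0.7)
  expect_lt(max(abs(compute_norm(rot) - compute_norm(tr)) /
                  pmax(compute_norm(tr), 1e-12)), 1e-12)
})

test_that("rot_x is a proper rotation and correction undoes a roll offset", {
  for (a in seq(-3, 3, length.out = 10)) {
    R <- rot_x(a)
    expect_equal(det(R), 1)
    expect_equal(R %*% rot_x(-a), diag(3), tolerance = 1e-12)
  }
  # identity at alpha = 0
  tr <- constant_trace(4, X = 0.1, Y = 0.2, Z = 0.9)
  expect_equal(apply_rotation_correction(tr, 0), tr)
  # a vector observed with roll pi/2 is brought back to the reference
  tr2 <- constant_trace(1, X = 0, Y = 1, Z = 0)
  out <- apply_rotation_correction(tr2, pi / 2)
  expect_equal(c(out$X, out$Y, out$Z), c(0, 0, 1), tolerance = 1e-12)
})

test_that("an injected 30-degree collar offset is recovered and corrected", {
  eth <- default_ethogram()
  sens <- sensor_params(drift = "constant", roll_offset_deg = 30)
  sch <- make_behavior_schedule(eth, 600, seed = 3)
  tr <- synthesize_trace(sch, eth, sens, seed = 4)
  pr <- process_trace(tr)
  corr <- estimate_collar_offset(pr)
  a_deg <- corr$alpha[["ind1"]] * 180 / pi
  expect_lt(abs(a_deg - 30), 2)
  # idempotence: correcting then re-estimating gives ~0
  tr2 <- apply_rotation_correction(tr, corr)
  attr(tr2, "rate_hz") <- 10
  a2 <- estimate_collar_offset(process_trace(tr2))$alpha[["ind1"]] * 180 / pi
  expect_lt(abs(a2), 2)
  # without drift the estimate is ~0
  tr0 <- synthesize_trace(sch, eth, sensor_params(), seed = 4)
  a0 <- estimate_collar_offset(process_trace(tr0))$alpha[["ind1"]] * 180 / pi
  expect_lt(abs(a0), 2)
})

test_that("windowed offset estimation tracks a slowly varying drift", {
  eth <- default_ethogram()[4, ]    # inactivity: quiet signal
  eth$weight <- 1
  sens <- sensor_params(drift = "random_walk", roll_offset_deg = 20,
                        drift_sd_deg_per_min = 3)
  sch <- make_behavior_schedule(eth, 900, seed = 5)
  set.seed(6)
  tr <- synthesize_trace(sch, eth, sens, seed = 6)
  pr <- process_trace(tr)
  expect_error(estimate_collar_offset(pr, window_s = 0.2), "3 samples")
  corr <- estimate_collar_offset(pr, window_s = 60)
  a <- corr$alpha[["ind1"]]
  expect_equal(length(a), nrow(tr))
  # drift stays in the vicinity of its 20-degree start
  expect_lt(abs(mean(a) * 180 / pi - 20), 10)
})

test_that("pitch recovers simulator head angles within 2 degrees", {
  eth <- default_ethogram()
  eth$noise_sd_g <- 0.05
  sch <- make_behavior_schedule(eth, 600, seed = 31)
  tr <- synthesize_trace(sch, eth, seed = 32, env_sd = 0, phase_jitter = 0)
  pr <- process_trace(tr)
  long <- sch[sch$stop_s - sch$start_s > 15, ]
  for (r in seq_len(nrow(long))) {
    i <- which(tr$time_s >= long$start_s[r] + 5 & tr$time_s < long$stop_s[r] - 5)
    if (length(i) < 50) next
    truth <- eth$head_angle_deg[match(long$behavior[r], eth$behavior)]
    est <- mean(pr$pitch[i]) * 180 / pi
    expect_lt(abs(est - truth), 2)
  }
})

test_that("class merging maps the full ethogram onto exactly 7 training classes", {
  map <- ethogram_class_map()
  merged <- setdiff(unique(map), NA)
  expect_length(merged, 7L)
  expect_setequal(merged, c("grazing", "browsing_low", "browsing_high",
                            "inactivity", "walking", "trotting", "other"))
  expect_equal(unname(map[["ruminating"]]), "inactivity")
  expect_equal(unname(map[["running"]]), "trotting")
  expect_equal(unname(map[["grazing while walking"]]), "grazing")
  expect_true(is.na(map[["missing data"]]))
})

test_that("annotation assigns interval labels, merges classes and flags gaps", {
  tr <- constant_trace(100)
  pr <- process_trace(tr)
  ann <- data.frame(id = "c1",
                    behavior = c("Ruminating", "running", "missing data"),
                    start_s = c(0, 3, 6), stop_s = c(3, 6, 8))
  out <- annotate_samples(pr, ann)
  expect_equal(unique(out$label[tr$time_s < 3]), "inactivity")
  expect_equal(unique(out$label[tr$time_s >= 3 & tr$time_s < 6]), "trotting")
  expect_equal(unique(out$label[tr$time_s >= 6]), "unlabelled")
  # empty annotations: everything unlabelled
  empty <- ann[0, ]
  expect_true(all(annotate_samples(pr, empty)$label == "unlabelled"))
  # unknown label is a hard error naming the offender
  bad <- data.frame(id = "c1", behavior = "levitating", start_s = 0, stop_s = 1)
  expect_error(annotate_samples(pr, bad), "levitating")
})

test_that("degenerate all-zero static vectors yield zero angles and are counted", {
  tr <- constant_trace(40, X = 0, Y = 0, Z = 0)
  pr <- process_trace(tr)
  expect_equal(attr(pr, "n_degenerate"), 40L)
  expect_true(all(pr$roll == 0))
  expect_true(all(pr$pitch == 0))
})
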