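# Behaviour schedules, signal synthesis, quantization, CSV round trips.

test_that("schedule generation validates its arguments", {
  eth <- default_ethogram()
  expect_error(make_behavior_schedule(eth, 0), "positive")
  expect_error(make_behavior_schedule(eth, -5), "positive")
  expect_error(make_behavior_schedule(data.frame(), 100), "non-empty")
  bad <- eth; bad$dyn_freq_hz[1] <- 6
  expect_error(make_behavior_schedule(bad, 100), "5")
})

test_that("a single-behaviour ethogram yields one interval spanning the schedule", {
  eth <- default_ethogram()[3, ]
  sch <- make_behavior_schedule(eth, 600, seed = 1)
  expect_equal(nrow(sch), 1L)
  expect_equal(sch$start_s, 0)
  expect_equal(sch$stop_s, 600)
  expect_equal(sch$behavior, "browsing_high")
})

test_that("dwell times are exponential with the configured mean", {
  eth <- data.frame(behavior = c("a", "b"), weight = c(0.5, 0.5),
                    mean_dwell_s = c(10, 10), head_angle_deg = c(0, 0),
                    dyn_amp_g = c(0, 0), dyn_freq_hz = c(1, 1),
                    noise_sd_g = c(0, 0))
  sch <- make_behavior_schedule(eth, 1e5, seed = 42)
  dwell <- sch$stop_s - sch$start_s
  dwell <- dwell[-length(dwell)]          # last bout is truncated
  expect_lt(abs(mean(dwell) - 10) / 10, 0.05)
  # strict alternation
  expect_true(all(sch$behavior[-1] != sch$behavior[-nrow(sch)]))
})

test_that("long-run time-in-behaviour fractions match the occupancy weights", {
  eth <- default_ethogram()
  sch <- make_behavior_schedule(eth, 2e5, seed = 11)
  dwell <- sch$stop_s - sch$start_s
  frac <- tapply(dwell, sch$behavior, sum) / sum(dwell)
  w <- setNames(eth$weight / sum(eth$weight), eth$behavior)
  n_bouts <- nrow(sch)
  for (b in eth$behavior) {
    se <- sqrt(w[b] * (1 - w[b]) / n_bouts)
    expect_lt(abs(frac[[b]] - w[[b]]), 3 * se + 0.01)
  }
})

test_that("schedules and traces are deterministic under a fixed seed", {
  eth <- default_ethogram()
  s1 <- make_behavior_schedule(eth, 500, seed = 9)
  s2 <- make_behavior_schedule(eth, 500, seed = 9)
  expect_identical(s1, s2)
  t1 <- synthesize_trace(s1, eth, seed = 3)
  t2 <- synthesize_trace(s2, eth, seed = 3)
  expect_identical(t1, t2)
  d1 <- simulate_dataset(2, 120, seed = 5)
  d2 <- simulate_dataset(2, 120, seed = 5)
  expect_identical(d1$trace, d2$trace)
  expect_identical(d1$annotations, d2$annotations)
})

test_that("the deterministic limit reproduces the quantized gravity vector", {
  eth <- data.frame(behavior = "still", weight = 1, mean_dwell_s = 60,
                    head_angle_deg = 0, dyn_amp_g = 0, dyn_freq_hz = 0,
                    noise_sd_g = 0)
  sch <- make_behavior_schedule(eth, 30, seed = 1)
  tr <- synthesize_trace(sch, eth, sensor_params(), seed = 1)
  step <- 16 / 255
  expect_true(all(tr$X == 0))
  expect_true(all(tr$Y == 0))
  expect_true(all(tr$Z == round(1 / step) * step))
  expect_equal(nrow(tr), 300L)           # floor(duration * rate)
})

test_that("samples live on the 8-bit quantization grid within the range", {
  ds <- simulate_dataset(1, 60, seed = 3)
  step <- 16 / 255
  for (ax in c("X", "Y", "Z")) {
    v <- ds$trace[[ax]]
    expect_true(all(abs(v / step - round(v / step)) < 1e-9))
    expect_true(all(abs(v) <= 8))
  }
})

test_that("quantization saturates at the configured range", {
  sens <- sensor_params(range_g = 1, bits = 8)
  expect_equal(collarHMM:::quantize_g(3, sens), 1)
  expect_equal(collarHMM:::quantize_g(-42, sens), -1)
})

test_that("the dynamic component's periodogram peaks at the configured frequency", {
  eth <- data.frame(behavior = "walk", weight = 1, mean_dwell_s = 1e4,
                    head_angle_deg = 0, dyn_amp_g = 0.5, dyn_freq_hz = 1.5,
                    noise_sd_g = 0.05)
  sch <- make_behavior_schedule(eth, 1000, seed = 1)
  tr <- synthesize_trace(sch, eth, seed = 2)
  x <- tr$X - mean(tr$X)                  # 1e4 samples at 10 Hz
  spec <- Mod(fft(x))^2
  freqs <- (seq_along(x) - 1) * 10 / length(x)
  keep <- freqs > 0 & freqs <= 5
  peak <- freqs[keep][which.max(spec[keep])]
  expect_lt(abs(peak - 1.5), 0.1)
})

test_that("a schedule with labels missing from the ethogram is rejected", {
  eth <- default_ethogram()
  sch <- data.frame(behavior = "flying", start_s = 0, stop_s = 10)
  expect_error(synthesize_trace(sch, eth), "flying")
})

test_that("with drift disabled the running mean recovers each behaviour's gravity vector", {
  eth <- default_ethogram()
  eth$noise_sd_g <- 0.03
  sch <- make_behavior_schedule(eth, 600, seed = 21)
  tr <- synthesize_trace(sch, eth, seed = 22, env_sd = 0, phase_jitter = 0)
  pr <- process_trace(tr)
  step <- 16 / 255
  rate <- 10
  # interior samples of long bouts only (5-s margin for the smoother)
  long <- sch[sch$stop_s - sch$start_s > 12, ]
  for (r in seq_len(nrow(long))) {
    i <- which(tr$time_s >= long$start_s[r] + 5 & tr$time_s < long$stop_s[r] - 5)
    if (length(i) < 10) next
    a <- eth$head_angle_deg[match(long$behavior[r], eth$behavior)] * pi / 180
    n_eff <- length(i)
    tol <- step + 3 * 0.03 / sqrt(51)
    expect_lt(abs(mean(pr$sX[i]) - (-sin(a))), tol)
    expect_lt(abs(mean(pr$sZ[i]) - cos(a)), tol)
  }
})

test_that("dataset CSV round trip preserves traces and annotations", {
  dir <- withr::local_tempdir()
  ds <- simulate_dataset(2, 90, seed = 13)
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$trace$X, ds$trace$X)
  expect_equal(back$trace$Y, ds$trace$Y)
  expect_equal(back$trace$Z, ds$trace$Z)
  expect_equal(back$trace$id, ds$trace$id)
  expect_equal(back$trace$time_s, ds$trace$time_s, tolerance = 1e-3)
  expect_equal(attr(back$trace, "rate_hz"), 10)
  ann <- back$annotations
  expect_equal(ann$behavior, ds$annotations$behavior)
  expect_equal(ann$start_s, ds$annotations$start_s, tolerance = 1e-9)
})

test_that("an empty annotation file reads back as an empty set", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("subject,behavior,start_s,stop_s", f)
  ann <- read_annotations_csv(f)
  expect_equal(nrow(ann), 0L)
  expect_named(ann, c("id", "behavior", "start_s", "stop_s"))
})

test_that("malformed files are rejected with the offending line number", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("tag_id,datetime,accX,accY,accZ",
               "t1,2020-03-01T06:00:00.000,0,0,1",
               "t1,2020-03-01T06:00:00.100,0,0,1",
               "t1,2020-03-01T06:00:00.050,0,0,1"), f)
  expect_error(read_accel_csv(f), "line 4")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject,behavior,start_s,stop_s",
               "a,grazing,0,10", "a,walking,10,8"), f2)
  expect_error(read_annotations_csv(f2), "line 3")
})
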