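test_that("volt-to-degree calibration applies the affine map and screen geometry", {
  t <- seq(0, 0.5, by = 0.001)
  # identity mapping, pre-converted degrees scaled back to pixels
  k <- degPerPixel(100, 51, 1440)
  g <- calibrateGaze(t, rep(3 / k, length(t)), rep(0, length(t)))
  expect_equal(g@x, rep(3, length(t)), tolerance = 1e-12)
  # gain 2, offset 0: raw 1.5 -> pixel 3.0
  g2 <- calibrateGaze(t, rep(1.5, length(t)), rep(0, length(t)),
                      mapping = list(gainX = 2))
  expect_equal(g2@x / k, rep(3, length(t)), tolerance = 1e-12)
  expect_error(calibrateGaze(t, t, t, mapping = list(gainX = Inf)), "finite")
})

test_that("pixel-degree round trip is exact to numerical precision", {
  k <- degPerPixel(100, 51, 1440)
  expect_equal(k, (180 / pi) * atan((51 / 1440) / 100))
  deg <- c(-14, -7, 0, 3.3, 7)
  px <- deg / k
  expect_lt(max(abs(px * k - deg)), 1e-9)
})

test_that("clock alignment shifts gaze earlier by the lag", {
  t <- seq(0, 1, by = 0.001)
  g <- calibrateGaze(t, t, t)
  a <- alignClocks(g, lag = 0.007)
  expect_equal(a@t, t - 0.007)
  expect_equal(round((g@t[101] - a@t[101]) * g@sfreq), 7)  # 7-sample shift
  expect_identical(alignClocks(g, 0)@t, g@t)
  # an event recorded at 0.100 maps to 0.093
  expect_equal(a@t[which(g@t == 0.100)], 0.093)
  expect_error(alignClocks(g, lag = 2), "exceeds")
})

test_that("a clean 10-degree saccade is found within 4 ms of its onset", {
  g <- syntheticGaze(onsets = 0.3, amplitudes = 10, duration = 1, seed = 3)
  ev <- eventTable(detectSaccades(g))
  big <- ev[ev$amplitude > 1, ]
  expect_equal(nrow(big), 1)
  expect_lt(abs(big$onset_t - 0.3), 0.004)
  expect_equal(big$amplitude, 10, tolerance = 0.15)
  expect_gt(big$peak_velocity, 200)
})

test_that("pure fixation jitter yields no events above one degree", {
  g <- syntheticGaze(onsets = numeric(0), amplitudes = numeric(0),
                     duration = 2, jitterSd = 0.05, seed = 4)
  ev <- eventTable(detectSaccades(g))
  expect_true(nrow(ev) == 0 || all(ev$amplitude <= 1))
})

test_that("two saccades 30 ms apart merge into a single surviving event", {
  g <- syntheticGaze(onsets = c(0.3, 0.36), amplitudes = c(5, 5),
                     duration = 1, jitterSd = 0.02, seed = 5)
  # offsets: first ends ~0.332, second starts 0.36 -> ~28 ms gap < 40 ms
  ev <- eventTable(detectSaccades(g))
  expect_equal(nrow(ev[ev$amplitude > 1 | ev$peak_velocity > 100, ]), 1)
})

test_that("events never overlap and gaps respect the minimum fixation duration", {
  g <- syntheticGaze(onsets = seq(0.3, 2.6, by = 0.23),
                     amplitudes = rep(c(3, 8), 6)[1:11], duration = 3,
                     seed = 6)
  ev <- eventTable(detectSaccades(g))
  if (nrow(ev) > 1) {
    gaps <- ev$onset_t[-1] - ev$offset_t[-nrow(ev)]
    expect_true(all(gaps >= 0.040))
  }
})

test_that("threshold iteration converges within its iteration budget", {
  p <- detectorParams()
  set.seed(8)
  for (scale in c(0.5, 2, 20)) {
    speed <- abs(stats::rnorm(5000, 0, scale))
    expect_silent(pt <- presaccade:::.adaptiveThreshold(speed, p))
    expect_true(is.finite(pt) && pt > 0)
  }
})

test_that("microsaccade partition is exhaustive, disjoint and boundary-inclusive", {
  e <- data.frame(onset_t = c(1, 2, 3), offset_t = c(1.02, 2.02, 3.02),
                  onset_idx = c(0, 10, 20), offset_idx = c(5, 15, 25),
                  amplitude = c(0.2, 0.5, 0.6), peak_velocity = c(30, 40, 50),
                  start_x = 0, start_y = 0, end_x = 0, end_y = 0)
  ev <- methods::new("SaccadeEvents", events = e, params = list())
  parts <- classifyMicrosaccades(ev, detectorParams())
  expect_equal(eventTable(parts$microsaccades)$amplitude, c(0.2, 0.5))
  expect_equal(eventTable(parts$saccades)$amplitude, 0.6)
  # empty input -> two empty partitions
  ev0 <- methods::new("SaccadeEvents", events = e[0, ], params = list())
  p0 <- classifyMicrosaccades(ev0)
  expect_equal(nrow(eventTable(p0$saccades)), 0)
  expect_equal(nrow(eventTable(p0$microsaccades)), 0)
  # all above the bound -> all saccades
  e2 <- transform(e, amplitude = amplitude + 1)
  p2 <- classifyMicrosaccades(methods::new("SaccadeEvents", events = e2,
                                           params = list()))
  expect_equal(nrow(eventTable(p2$microsaccades)), 0)
})

test_that("invalid gaze is handled: all-invalid warns, blinks are excluded", {
  g <- syntheticGaze(onsets = 0.5, amplitudes = 8, duration = 1, seed = 7)
  gAll <- g; gAll@valid <- rep(FALSE, length(g@t))
  expect_warning(ev <- detectSaccades(gAll), "invalid")
  expect_equal(nrow(eventTable(ev)), 0)
})

test_that("gaze TSV round-trips including invalid samples", {
  g <- syntheticGaze(onsets = 0.3, amplitudes = 5, duration = 0.6, seed = 9)
  g@valid[100:120] <- FALSE
  path <- tempfile(fileext = ".tsv")
  writeGazeTsv(g, path)
  back <- readGazeTsv(path)
  expect_equal(back@valid, g@valid)
  expect_equal(back@x[g@valid], g@x[g@valid], tolerance = 1e-6)
  expect_equal(back@t, g@t, tolerance = 1e-9)
})
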