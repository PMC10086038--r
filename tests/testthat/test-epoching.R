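test_that("DFT notch removes line components and preserves everything else", {
  sf <- 1000
  tt <- seq(0, 2 - 1 / sf, by = 1 / sf)          # integer number of cycles
  line <- sin(2 * pi * 50 * tt) + 0.5 * cos(2 * pi * 150 * tt)
  out <- dftNotch(rbind(line), sf)
  expect_lt(sqrt(mean(out^2)) / sqrt(mean(line^2)), 1e-8)
  # DC unchanged
  expect_equal(as.numeric(dftNotch(rbind(rep(2, length(tt))), sf)),
               rep(2, length(tt)), tolerance = 1e-9)
  # 10 Hz amplitude preserved
  s10 <- sin(2 * pi * 10 * tt)
  out10 <- dftNotch(rbind(s10 + line), sf)
  expect_equal(max(abs(out10)), 1, tolerance = 1e-6)
  expect_lt(max(abs(out10 - s10)), 1e-6)
  expect_error(dftNotch(rbind(s10), sfreq = 200, freqs = c(50, 100, 150)),
               "Nyquist")
})

test_that("downsampling halves the sample count and preserves the passband", {
  sf <- 1000
  n <- 2000
  tt <- (seq_len(n) - 1) / sf
  x <- sin(2 * pi * 10 * tt)
  ep <- makeEpochs(rbind(a = x, b = rep(1, n)), sf, onsets = 1,
                   window = c(-1.000, 0.999))
  expect_equal(dim(epochData(ep))[3], 2000)
  dn <- downsampleEpochs(ep, 500)
  expect_equal(dim(epochData(dn))[3], 1000)
  expect_equal(dn@sfreq, 500)
  # DC exactly preserved
  expect_equal(as.numeric(epochData(dn)[1, 2, ]), rep(1, 1000),
               tolerance = 1e-6)
  # 10 Hz amplitude within 1 %
  mid <- epochData(dn)[1, 1, 100:900]
  expect_equal(max(abs(mid)), 1, tolerance = 0.01)
  expect_error(downsampleEpochs(ep, 300), "divide")
  expect_identical(downsampleEpochs(dn, 500), dn)   # no-op at target rate
})

test_that("photodiode trinary conversion follows the linear-boundary rule", {
  expect_equal(photodiodeTrinary(c(0, 1.5, 3)), c(-1L, 0L, 1L))
  expect_equal(photodiodeTrinary(c(0, 0, 3, 3)), c(-1L, -1L, 1L, 1L))
  expect_error(photodiodeTrinary(rep(5, 10)), "zero range")
  # boundary samples: b2 = 1, b3 = 2 for range [0, 3]; values in [1, 2] -> 0
  expect_equal(photodiodeTrinary(c(0, 1, 2, 3)), c(-1L, 0L, 0L, 1L))
  # interior-boundaries variant uses 4 boundaries strictly inside the range
  expect_equal(photodiodeTrinary(c(0, 1.5, 3), includeExtremes = FALSE),
               c(-1L, 0L, 1L))
})

test_that("visual onsets sit at the later sample of each trinary change", {
  expect_equal(visualOnsets(c(-1, -1, 1, 1), 500), 0.004)
  expect_equal(visualOnsets(rep(0, 10), 500), numeric(0))
  expect_equal(visualOnsets(c(0, 1, 0), 500), c(0.002, 0.004))
})

test_that("the six-trial toy table leaves exactly one surviving saccade trial", {
  trials <- data.frame(
    trial = 1:6,
    n_saccades = c(2, 1, 1, 1, 1, 1),
    end_x = c(-7, -3, -7, -7, -7, -7),
    end_y = c(0, 0, -3, 0, 0, 0),
    latency = c(0.3, 0.3, 0.3, 0.120, 0.600, 0.3))
  sel <- selectSaccadeTrials(trials)
  expect_equal(sum(sel$keep), 1)
  expect_equal(trials$trial[sel$keep], 6)
  expect_equal(sel$log$rule,
               c("single_saccade", "endpoint_crossing", "endpoint_height",
                 "latency_window", "latency_window"))
  # conservation: retained + rejected = input
  expect_equal(sum(sel$keep) + nrow(sel$log), nrow(trials))
})

test_that("latency bounds are inclusive and compliant tables are fully retained", {
  trials <- data.frame(trial = 1:3, n_saccades = 1, end_x = -7, end_y = 0,
                       latency = c(0.150, 0.500, 0.3))
  sel <- selectSaccadeTrials(trials)
  expect_true(all(sel$keep))
  expect_equal(nrow(sel$log), 0)
})

test_that("fixation rules reject excursions and large microsaccades", {
  trials <- data.frame(trial = 1:4,
                       max_gaze_excursion = c(2.5, 0.1, 0.1, 0.1),
                       max_microsaccade = c(0, 0.7, 0.3, NA))
  sel <- selectFixationTrials(trials)
  expect_equal(sel$keep, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(sel$log$rule, c("gaze_excursion", "microsaccade"))
})

test_that("relocking places stimulus onset at minus latency and drops short trials", {
  setup <- zeroNoiseSetup(nPer = 6, seed = 19)
  rows <- setup$rows$saccade_stimulus
  lat <- setup$meta$latency[rows]
  rl <- relockToSaccade(subsetEpochs(setup$epochs, rows), lat)
  ep <- rl$epochs
  expect_equal(range(epochTimes(ep)), c(-0.6, 0))
  expect_equal(dim(epochData(ep))[3], 301)
  # the stimulus-onset sample carries the photodiode-step-locked kernel:
  # verify time axis arithmetic instead via metadata
  expect_equal(epochTimes(ep)[301], 0)
  # a trial relocked at latency L uses data from stimulus time L - 0.6
  expect_true(all(lat - 0.6 >= setup$epochs@t[1]))
  # onset too early for coverage -> dropped, not an error
  rl2 <- relockToSaccade(subsetEpochs(setup$epochs, rows),
                         c(0.05, lat[-1]))
  expect_equal(rl2$dropped, 1L)
  expect_equal(nTrials(rl2$epochs), length(rows) - 1L)
})

test_that("notch and downsample commute with epoching on synthetic data", {
  sf <- 1000
  n <- 6000
  tt <- (seq_len(n) - 1) / sf
  x <- rbind(ch1 = sin(2 * pi * 10 * tt) + 0.8 * sin(2 * pi * 50 * tt) +
               0.3 * cos(2 * pi * 100 * tt))
  onsets <- c(2, 4)
  # notch the continuous trace, then epoch, then downsample
  a <- downsampleEpochs(makeEpochs(dftNotch(x, sf), sf, onsets,
                                   c(-0.5, 1.0), channels = "ch1"), 500)
  # epoch first, then notch each epoch (integer cycles in both windows)
  b <- makeEpochs(x, sf, onsets, c(-0.5, 1.0), channels = "ch1")
  b@data[1, 1, ] <- dftNotch(b@data[1, 1, ], sf)
  b@data[2, 1, ] <- dftNotch(b@data[2, 1, ], sf)
  b <- downsampleEpochs(b, 500)
  rms <- sqrt(mean(a@data^2))
  expect_lt(max(abs(a@data - b@data)) / rms, 1e-6)
})

test_that("the artifact annotator flags amplitude, z-score and manual rejections", {
  set.seed(41)
  d <- array(rnorm(10 * 2 * 50), c(10, 2, 50))
  d[3, 1, 20] <- 40           # z-score outlier
  d[7, 2, 10] <- 500          # absolute-amplitude outlier
  ep <- methods::new("EpochSet", data = d, t = (1:50) / 500, sfreq = 500,
                     meta = data.frame(trial = 1:10), lock = "stimulus_onset",
                     channels = c("a", "b"))
  ann <- annotateArtifacts(ep, zThreshold = 8, absThreshold = 100)
  expect_false(ann$keep[3])
  expect_false(ann$keep[7])
  expect_equal(sum(!ann$keep), 2)
  expect_setequal(ann$log$rule, c("zscore", "amplitude"))
  # manual mask file with 0-based indices
  f <- tempfile()
  writeLines("4", f)
  ann2 <- annotateArtifacts(ep, zThreshold = 8, absThreshold = 100,
                            manualMask = f)
  expect_false(ann2$keep[5])
  expect_true("manual" %in% ann2$log$rule)
  # conservation
  expect_equal(sum(ann2$keep) + nrow(ann2$log), 10)
})
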