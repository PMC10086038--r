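test_that("latency KDEs integrate to one over the support", {
  set.seed(1)
  lat <- runif(40, 0.2, 0.4)
  kde <- fitLatencyKde(lat)
  grid <- seq(0.15, 0.5, length.out = 2001)
  mass <- sum(evalLatencyKde(kde, grid)) * diff(grid[1:2])
  expect_equal(mass, 1, tolerance = 1e-3)
  expect_equal(evalLatencyKde(kde, c(0.1, 0.6)), c(0, 0))
  expect_error(fitLatencyKde(c(0.2, 0.3)), "at least 5")
})

test_that("degenerate latencies concentrate at the shared value with the bandwidth floor", {
  kde <- fitLatencyKde(rep(0.250, 10))
  expect_equal(kde@bandwidth, 0.005)
  draws <- sampleOnsets(kde, nDraws = 500, seed = 3)
  expect_equal(unname(ncol(draws)), 500)
  expect_lt(max(abs(draws - 0.250)), 5 * 0.005)
})

test_that("sampled onsets reproduce the source distribution (KS distance)", {
  set.seed(5)
  lat <- runif(1000, 0.2, 0.4)
  kde <- fitLatencyKde(lat)
  draws <- as.vector(sampleOnsets(kde, nDraws = 2000, seed = 8))
  ks <- suppressWarnings(stats::ks.test(draws, lat))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("onset sampling is deterministic, feature-matched and support-bounded", {
  feats <- expand.grid(orientation = c(-30, 30),
                       spatial_frequency = c(0.33, 1.33),
                       phase = c(0, pi))
  feats <- feats[rep(1:8, 3), ]
  set.seed(2)
  lats <- 0.15 + 0.35 * rbeta(nrow(feats), 2, 3)
  kdes <- fitLatencyKdes(lats, feats)
  expect_length(kdes, 8)
  on1 <- sampleOnsets(kdes, feats[1:6, ], nDraws = 100, seed = 4)
  on2 <- sampleOnsets(kdes, feats[1:6, ], nDraws = 100, seed = 4)
  expect_identical(on1, on2)
  expect_equal(dim(on1), c(6L, 100L))
  expect_true(all(on1 >= 0.15 & on1 <= 0.5))
  expect_error(sampleOnsets(kdes["30|0.33|0"],
                            data.frame(orientation = -30,
                                       spatial_frequency = 0.33, phase = 0),
                            10, 1),
               "no KDE")
  # sparse cells fall back to the pooled estimate with a warning
  expect_warning(fitLatencyKdes(lats[1:10], feats[1:10, ]), "pooled")
})

test_that("identity alignment reproduces the stimulus-locked evoked response", {
  setup <- zeroNoiseSetup(nPer = 8, seed = 25)
  lay <- setup$cfg$layout
  rows <- setup$rows$stimulus_only
  stimEp <- subsetEpochs(setup$epochs, rows)
  # all simulated onsets equal: relocking is a constant shift, so the
  # surrogate template equals the stimulus-locked evoked on those samples
  L <- 0.3
  on <- matrix(L, nrow = length(rows), ncol = 1)
  avg <- combinePlanar(averageEvoked(stimEp), lay)
  sel <- which(stimEp@t >= L - 0.6 - 1e-9 & stimEp@t <= L + 1e-9)
  direct <- baselineCorrect(avg[, sel], stimEp@t[sel] - L,
                            condition = "stimulus_only")
  xsEv <- relockedEvoked(setup, "saccade_only", lay)
  # feeding the direct template back as the response must yield weights
  # (0, 1) and a vanishing residual
  sr <- surrogateResiduals(stimEp, on, lay, direct, xsEv, keepBetas = TRUE)
  expect_lt(max(abs(sr@betaSaccade)), 1e-9)
  expect_lt(max(abs(sr@betaStimulus - 1)), 1e-9)
  expect_lt(max(abs(medianResidualTraces(sr))), 1e-9)
})

test_that("latency scattering smears a transient response (peak shrinks)", {
  setup <- zeroNoiseSetup(nPer = 10, seed = 26)
  lay <- setup$cfg$layout
  rows <- setup$rows$stimulus_only
  stimEp <- subsetEpochs(setup$epochs, rows)
  n <- length(rows)
  set.seed(6)
  template <- function(onsets) {
    rl <- relockToSaccade(stimEp, onsets)$epochs
    max(evokedGradient(rl, lay)@values)
  }
  aligned <- template(rep(0.3, n))
  scattered <- template(runif(n, 0.15, 0.5))
  expect_gt(aligned, scattered)
})

test_that("median reduction is robust and validates the draw count", {
  set.seed(7)
  base <- array(rnorm(40 * 3 * 10), c(40, 3, 10))
  m <- medianResiduals(base, nDraws = 40)
  expect_equal(dim(medianResidualTraces(m)), c(3L, 10L))
  # identical draws: median equals any single draw
  same <- array(rep(base[1, , ], each = 5), c(5, 3, 10))
  expect_equal(medianResidualTraces(medianResiduals(same)), base[1, , ],
               ignore_attr = TRUE)
  # a single extreme outlier only nudges the median between adjacent
  # order statistics
  pert <- base[1:39, , ]
  out1 <- medianResidualTraces(medianResiduals(pert))
  pert2 <- pert3 <- array(0, c(40, 3, 10))
  pert2[1:39, , ] <- pert; pert2[40, , ] <- 1e6
  pert3[1:39, , ] <- pert; pert3[40, , ] <- -1e6
  med2 <- medianResidualTraces(medianResiduals(pert2))
  med3 <- medianResidualTraces(medianResiduals(pert3))
  expect_true(all(med3 <= out1 + 1e-12 & out1 <= med2 + 1e-12))
  expect_lt(max(abs(med2 - med3)), max(abs(pert)) * 2)
  # symmetric +v/-v pairs plus a zero trace have median zero
  v <- array(0, c(3, 2, 4))
  v[1, , ] <- 2; v[2, , ] <- -2
  expect_true(all(medianResidualTraces(medianResiduals(v)) == 0))
  expect_error(medianResiduals(base, nDraws = 39), "expected 39")
})

test_that("the surrogate chain is deterministic given config and seed", {
  setup <- zeroNoiseSetup(nPer = 6, seed = 27,
                          noise = c(white = 0.5, pink = 0.5))
  lay <- setup$cfg$layout
  rows <- setup$rows$stimulus_only
  kde <- fitLatencyKde(setup$meta$latency[setup$rows$saccade_stimulus])
  runOnce <- function() {
    on <- sampleOnsets(kde, data.frame(trial = seq_along(rows)),
                       nDraws = 25, seed = 99)
    yEv <- relockedEvoked(setup, "saccade_stimulus", lay)
    xsEv <- relockedEvoked(setup, "saccade_only", lay)
    surrogateResiduals(subsetEpochs(setup$epochs, rows), on, lay, yEv, xsEv,
                       seed = 99)
  }
  a <- runOnce(); b <- runOnce()
  expect_identical(medianResidualTraces(a), medianResidualTraces(b))
  expect_equal(a@nDraws, 25L)
})

test_that("runtime grows roughly linearly in the number of draws", {
  setup <- zeroNoiseSetup(nPer = 8, seed = 28,
                          noise = c(white = 0.5, pink = 0.5))
  lay <- setup$cfg$layout
  rows <- setup$rows$stimulus_only
  yEv <- relockedEvoked(setup, "saccade_stimulus", lay)
  xsEv <- relockedEvoked(setup, "saccade_only", lay)
  stimEp <- subsetEpochs(setup$epochs, rows)
  tm <- vapply(c(50, 400), function(nd) {
    set.seed(1)
    on <- matrix(runif(length(rows) * nd, 0.15, 0.5), length(rows), nd)
    system.time(surrogateResiduals(stimEp, on, lay, yEv, xsEv))[3]
  }, numeric(1))
  # 8x the draws should cost clearly less than ~30x (loose linearity bound)
  expect_lt(tm[2], max(0.05, tm[1]) * 30)
})
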