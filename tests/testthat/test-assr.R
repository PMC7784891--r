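test_that("z-scoring uses the pre-stimulus record and is idempotent", {
  fs <- 500
  nT <- round(1.5 * fs)
  set.seed(1)
  z <- as.numeric(scale(rnorm(10 * fs)))       # exact mean 0, sd 1
  prestim <- 5 + 2 * z
  x <- lfpFixture(matrix(9, 1, nT), fs = fs, prestim = prestim)
  xz <- zscoreLfp(x)
  expect_equal(trials(xz)[1, 1], 2.0, tolerance = 1e-12)
  expect_true(isNormalized(xz))
  xz2 <- zscoreLfp(xz)
  expect_equal(trials(xz2), trials(xz), tolerance = 1e-9)
  # flat record is degenerate
  flat <- lfpFixture(matrix(9, 1, nT), fs = fs, prestim = rep(1, 10 * fs))
  expect_error(zscoreLfp(flat), "sd is zero")
})

test_that("identical noise-free entrained trials give evoked == total", {
  fs <- 500
  tr <- sineTrial(fs, A = 2)
  x <- lfpFixture(matrix(rep(tr, 10), 10, byrow = TRUE,
                         ncol = length(tr)), fs = fs)
  ev <- assrPower(x, "evoked")$value
  to <- assrPower(x, "total")$value
  expect_equal(ev, to, tolerance = 1e-9)
  expect_gt(ev, 0)
})

test_that("evoked power never exceeds total power (both subtraction domains)", {
  fs <- 500
  set.seed(3)
  for (i in 1:8) {
    nT <- sample(2:12, 1)
    mat <- matrix(rnorm(nT * round(1.5 * fs), sd = runif(1, 0.5, 5)),
                  nrow = nT)
    if (i %% 2 == 0)   # add structured entrained component
      mat <- mat + t(replicate(nT, sineTrial(fs, A = runif(1, 0, 4),
                                             phi = runif(1, 0, 2 * pi))))
    mid <- matrix(rnorm(nT * round(0.2 * fs)), nrow = nT)
    x <- lfpFixture(mat, fs = fs, midIsi = mid)
    expect_lte(assrPower(x, "evoked")$value,
               assrPower(x, "total")$value + 1e-9)
    expect_lte(assrPower(x, "evoked", spontaneous = "trace")$value,
               assrPower(x, "total", spontaneous = "trace")$value + 1e-9)
  }
})

test_that("power metrics are invariant to trial order; ITC to amplitude rescaling", {
  p <- makePreset("control")
  x <- generateAssrTrials(p, nTrials = 12, seed = 9)
  perm <- c(7, 3, 12, 1, 10, 5, 2, 11, 8, 4, 9, 6)
  xp <- x
  xp@trials <- x@trials[perm, ]
  xp@midIsiSegments <- x@midIsiSegments[perm, ]
  expect_equal(assrPower(x, "evoked")$value, assrPower(xp, "evoked")$value)
  expect_equal(assrPower(x, "total")$value, assrPower(xp, "total")$value)
  expect_equal(intertrialCoherence(x)@bandMetric,
               intertrialCoherence(xp)@bandMetric)
  xs <- x
  xs@trials <- x@trials * 7.3
  expect_equal(intertrialCoherence(x)@bandMetric,
               intertrialCoherence(xs)@bandMetric, tolerance = 1e-9)
})

test_that("input validation: windows, mid-ISI and prestim requirements", {
  x <- generateAssrTrials(makePreset("control"), nTrials = 3, seed = 1)
  expect_error(assrPower(x, window = c(0.8, 1.2)), "outside the trial span")
  noIsi <- x
  noIsi@midIsiSegments <- matrix(0, 0, 0)
  expect_error(assrPower(noIsi), "mid-ISI")
  short <- x
  short@prestimRecord <- x@prestimRecord   # validity blocks <10 s; bypass slot
  short@prestimRecord <- x@prestimRecord[1:100]
  expect_error(baselinePower(short), "10 s")
})

test_that("baseline band power scales as amplitude squared (50 x 200-ms segments)", {
  p1 <- presetWith(baselineGammaAmp = 5, evokedAmp = 0, pinkNoiseSd = 0,
                   n1Amp = 0)
  p2 <- presetWith(baselineGammaAmp = 10, evokedAmp = 0, pinkNoiseSd = 0,
                   n1Amp = 0)
  b1 <- baselinePower(generateAssrTrials(p1, nTrials = 1, seed = 4))$value
  b2 <- baselinePower(generateAssrTrials(p2, nTrials = 1, seed = 4))$value
  expect_equal(b2 / b1, 4, tolerance = 1e-9)
})

test_that("ITC equals 1 for a single trial and stays within [0, 1]", {
  p <- makePreset("control")
  x1 <- generateAssrTrials(p, nTrials = 1, seed = 2)
  itc1 <- intertrialCoherence(x1)
  expect_equal(itc1@bandMetric, 1, tolerance = 1e-9)
  x <- generateAssrTrials(p, nTrials = 20, seed = 2)
  itc <- intertrialCoherence(x)
  v <- itc@values[!itc@excluded]
  expect_true(all(v >= 0 & v <= 1 + 1e-12))
})

test_that("N1 amplitude recovers a constructed dip and flags edge cases", {
  fs <- 500
  nT <- round(1.5 * fs)
  tt <- -0.5 + (seq_len(nT) - 1) / fs
  dip <- -50 * exp(-(tt - 0.04)^2 / (2 * 0.01^2))
  x <- lfpFixture(matrix(dip, 1, nT), fs = fs)
  r <- n1Amplitude(x)
  expect_equal(r$amplitude, 50, tolerance = 1e-6)
  expect_equal(r$time, 0.04, tolerance = 2 / fs)
  expect_true(r$localMinimum)
  flatx <- lfpFixture(matrix(0, 1, nT), fs = fs)
  rf <- n1Amplitude(flatx)
  expect_identical(rf$amplitude, 0)
  expect_false(rf$localMinimum)
})

test_that("aggregation per animal averages channels; per channel passes through", {
  m <- data.frame(subject = "s1", channel = c("ch1", "ch2", "ch3"),
                  condition = "control", metric = "evoked",
                  value = c(1, 2, 3))
  pa <- aggregateMetrics(m, "per_animal")
  expect_identical(nrow(pa), 1L)
  expect_identical(pa$value, 2)
  expect_identical(aggregateMetrics(m, "per_channel"), m)
  expect_error(aggregateMetrics(m[0, ], "per_animal"), "empty")
})
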