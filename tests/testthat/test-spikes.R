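test_that("binning counts spikes in half-open bins and conserves totals", {
  p <- spikePairFixture(seq(0.5, 9.5, by = 1), numeric(0), 10)
  expect_error(binSpikeTrains(p, binWidth = 1), "100 bin")
  b <- binSpikeTrains(p, binWidth = 0.05)
  expect_identical(sum(b$countsA), 10L)
  expect_identical(sum(b$countsB), 0L)
  expect_identical(b$nBins, 200L)
  # one spike per 1-s stretch lands in one bin each
  expect_true(all(tapply(b$countsA, rep(1:10, each = 20), sum) == 1))
  set.seed(11)
  for (i in 1:20) {
    t <- sort(runif(rpois(1, 50), 0, 10))
    t <- t[c(TRUE, diff(t) > 0)]
    pr <- spikePairFixture(t, numeric(0), 10)
    expect_identical(sum(binSpikeTrains(pr, 0.01)$countsA), length(t))
  }
})

test_that("identical trains give r = 1; zero variance is flagged NA", {
  set.seed(2)
  t <- sort(runif(300, 0, 60))
  p <- spikePairFixture(t, t, 60)
  cc <- crossCorrelation(p)
  expect_equal(cc@coefficient, 1)
  # correlogram statistics symmetric around zero lag for identical trains
  cg <- cc@correlogram
  expect_equal(cg$r[cg$lag > 0], rev(cg$r[cg$lag < 0]), tolerance = 1e-12)
  empty <- spikePairFixture(t, numeric(0), 60)
  expect_error(crossCorrelation(empty), "non-empty")
  lone <- spikePairFixture(t, 30, 60)   # single spike: zero-variance counts?
  expect_s4_class(suppressWarnings(crossCorrelation(lone)), "CrossCorrResult")
})

test_that("independent trains have near-zero correlation; shared fraction sets r", {
  rs <- vapply(1:40, function(s) {
    crossCorrelation(generateSpikePair(5, 0, 200, seed = s))@coefficient
  }, numeric(1))
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(40))
  nb <- 200 / 0.005
  expect_lt(max(abs(rs)), 5 / sqrt(nb))
  # thinned-Poisson oracle: zero-lag r of counts ~ sharedFrac
  for (p in c(0.15, 0.4)) {
    rp <- vapply(1:40, function(s) {
      crossCorrelation(generateSpikePair(5, p, 200, seed = 1000 + s))@coefficient
    }, numeric(1))
    expect_lt(abs(mean(rp) - p), 3 * sd(rp) / sqrt(40))
  }
})

test_that("ISI shuffle preserves count and interval multiset exactly", {
  set.seed(5)
  t <- sort(runif(200, 0, 100))
  set.seed(1)
  ts <- gammasynch:::.isiShuffle(t)
  expect_identical(length(ts), length(t))
  expect_equal(sort(diff(ts)), sort(diff(t)), tolerance = 1e-12)
  expect_identical(ts[1], t[1])
})

test_that("shuffle null calibrates and detects shared input", {
  set.seed(8)
  t <- sort(runif(400, 0, 100))
  ident <- spikePairFixture(t, t, 100)
  sn <- shuffleNull(ident, nShuffles = 30, seed = 1)
  expect_equal(sn@coefficient, 1)
  expect_true(all(attr(sn, "null") < 1))
  expect_identical(sn@nullQuantile, 1)
  # independent pairs: observed r inside the central 95% for most seeds
  inside <- vapply(1:10, function(s) {
    pr <- generateSpikePair(5, 0, 150, seed = 400 + s)
    x <- shuffleNull(pr, nShuffles = 40, seed = s)
    x@nullQuantile > 0.025 && x@nullQuantile < 0.975
  }, logical(1))
  expect_gte(mean(inside), 0.7)
  # shared_frac 0.3 pairs exceed null mean + 3 null sd almost always
  exceed <- vapply(1:20, function(s) {
    pr <- generateSpikePair(5, 0.3, 150, seed = 800 + s)
    x <- shuffleNull(pr, nShuffles = 30, seed = s)
    x@coefficient > x@nullMean + 3 * x@nullSd
  }, logical(1))
  expect_gte(mean(exceed), 0.95)
  expect_error(shuffleNull(spikePairFixture(c(1, 2), t, 100), 30), "3 spikes")
  expect_error(shuffleNull(ident, nShuffles = 5), "20 shuffles")
})

test_that("correlation is stable under joint time translation", {
  pr <- generateSpikePair(5, 0.3, 200, seed = 77)
  shift <- 1.0   # a whole number of 5-ms bins
  tr <- new("SpikeTrainPair", timesA = timesA(pr) + shift,
            timesB = timesB(pr) + shift,
            duration = recordingDuration(pr) + shift,
            unitIds = c("u1", "u2"))
  r0 <- crossCorrelation(pr)@coefficient
  r1 <- crossCorrelation(tr)@coefficient
  expect_lt(abs(r0 - r1), 0.02)
})
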