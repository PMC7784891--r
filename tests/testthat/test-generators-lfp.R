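test_that("identical (preset, seed) give bit-identical LFP output", {
  a <- generateAssrTrials(makePreset("control"), nTrials = 5, seed = 42)
  b <- generateAssrTrials(makePreset("control"), nTrials = 5, seed = 42)
  expect_identical(trials(a), trials(b))
  expect_identical(midIsiSegments(a), midIsiSegments(b))
  expect_identical(prestimRecord(a), prestimRecord(b))
  c <- generateAssrTrials(makePreset("control"), nTrials = 5, seed = 43)
  expect_false(identical(trials(a), trials(c)))
})

test_that("infinite phase concentration and zero noise give identical trials with ITC 1", {
  p <- presetWith(phaseKappa = Inf, pinkNoiseSd = 0, baselineGammaAmp = 0,
                  n1Amp = 0)
  x <- generateAssrTrials(p, nTrials = 10, seed = 1)
  expect_true(all(apply(trials(x), 2, function(col) length(unique(col)) == 1)))
  expect_equal(intertrialCoherence(x)@bandMetric, 1, tolerance = 1e-12)
})

test_that("without an evoked component, stimulus-band power matches mid-ISI power", {
  p <- presetWith(evokedAmp = 0, n1Amp = 0)
  x <- zscoreLfp(generateAssrTrials(p, nTrials = 50, seed = 5))
  # total power already subtracts the mid-ISI estimate: difference ~ 0
  expect_lt(abs(assrPower(x, "total")$value),
            0.15 * baselinePower(x)$value + 0.02)
})

test_that("uniform evoked phase gives evoked/total ~ 1/n (resultant-length oracle)", {
  # Monte-Carlo oracle: |mean of n iid uniform-phase unit vectors|^2
  n <- 50
  set.seed(99)
  oracle <- replicate(3000, Mod(mean(exp(1i * runif(n, 0, 2 * pi))))^2)
  oracleSE <- sd(oracle) / sqrt(30)
  expect_equal(mean(oracle), 1 / n, tolerance = 5 * sd(oracle) / sqrt(3000) / (1 / n))

  p <- presetWith(phaseKappa = 0, pinkNoiseSd = 0, baselineGammaAmp = 0,
                  n1Amp = 0)
  ratios <- vapply(1:30, function(s) {
    x <- generateAssrTrials(p, nTrials = n, seed = s)
    assrPower(x, "evoked")$value / assrPower(x, "total")$value
  }, numeric(1))
  expect_equal(mean(ratios), 1 / n, tolerance = 3 * oracleSE / (1 / n))
})

test_that("analysis round-trip recovers preset orderings across seeds", {
  # evoked power monotone in evokedAmp: rank correlation >= 0.9
  amps <- seq(5, 40, length.out = 20)
  ev <- vapply(seq_along(amps), function(i) {
    p <- presetWith(evokedAmp = amps[i])
    assrPower(zscoreLfp(generateAssrTrials(p, nTrials = 30, seed = 100 + i)),
              "evoked")$value
  }, numeric(1))
  expect_gte(cor(amps, ev, method = "spearman"), 0.9)

  # ITC monotone in phaseKappa; baseline power monotone in baselineGammaAmp
  kappas <- c(0.5, 2, 8)
  itc <- sapply(seq_along(kappas), function(k) {
    vapply(1:20, function(s) {
      p <- presetWith(phaseKappa = kappas[k])
      intertrialCoherence(
        generateAssrTrials(p, nTrials = 30, seed = 200 + s))@bandMetric
    }, numeric(1))
  })
  expect_true(all(diff(colMeans(itc)) > 0))
  bamps <- c(4, 8, 16)
  bp <- sapply(seq_along(bamps), function(k) {
    vapply(1:20, function(s) {
      p <- presetWith(baselineGammaAmp = bamps[k], evokedAmp = 0)
      baselinePower(generateAssrTrials(p, nTrials = 1, seed = 300 + s))$value
    }, numeric(1))
  })
  expect_true(all(diff(colMeans(bp)) > 0))
  # per-seed ordering holds for the vast majority of seeds
  expect_gte(mean(itc[, 3] > itc[, 1]), 0.95)
  expect_gte(mean(bp[, 3] > bp[, 1]), 0.95)
})

test_that("generator validates its inputs", {
  expect_error(generateAssrTrials(makePreset("control"), nTrials = 0), "nTrials")
  expect_error(generateAssrTrials(makePreset("control"), sampleRate = 250),
               "sampleRate")
})
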