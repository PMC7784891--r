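test_that("CTCF is integrated density minus area x background", {
  expect_identical(ctcf(1000, 50, 4), 800)
  expect_identical(ctcf(1000, 50, 0), 1000)
  expect_identical(ctcf(200, 50, 4), 0)
  expect_warning(neg <- ctcf(100, 50, 4), "negative")
  expect_identical(neg, -100)
  expect_error(ctcf(100, 0, 1), "area")
})

test_that("normalized fluorescence maps the reference mean to 100%", {
  cells <- data.frame(ctcf = c(700, 900, 1120),
                      group = c("ref", "ref", "pv"))
  out <- normalizedFluorescence(cells, cells$group == "ref")
  expect_equal(out$normalizedPct, c(87.5, 112.5, 140))
  expect_equal(mean(out$normalizedPct[cells$group == "ref"]), 100)
  allEq <- data.frame(ctcf = rep(640, 5))
  expect_true(all(normalizedFluorescence(allEq, rep(TRUE, 5))$normalizedPct == 100))
  expect_error(normalizedFluorescence(cells, rep(FALSE, 3)), "empty")
  expect_error(normalizedFluorescence(data.frame(ctcf = c(-1, 1)),
                                      c(TRUE, FALSE)), "> 0")
  # computed from raw ROI measurements too
  raw <- data.frame(integratedDensity = c(1000, 1240), area = c(50, 60),
                    backgroundMean = c(4, 4))
  out2 <- normalizedFluorescence(raw, c(TRUE, FALSE))
  expect_equal(out2$normalizedPct, c(100, 125))
})

test_that("alternation index scores overlapping distinct triplets", {
  expect_equal(alternationIndex(c("A", "B", "C", "A", "B", "C")), 100)
  expect_equal(alternationIndex(c("A", "B", "A", "B", "A")), 0)
  expect_equal(alternationIndex(c("A", "B", "C", "B", "A")), 2 / 3 * 100)
  expect_error(alternationIndex(c("A", "B")), "3 arm")
  expect_error(alternationIndex(c("A", "A", "B")), "consecutive")
  # invariant under arm relabeling
  set.seed(3)
  s <- armEntries(generateYmazeSession("lapse", 20, seed = 5, lapseProb = 0.4))
  for (perm in list(c(A = "B", B = "C", C = "A"), c(A = "C", B = "A", C = "B"),
                    c(A = "B", B = "A", C = "C")))
    expect_equal(alternationIndex(unname(perm[s])), alternationIndex(s))
})

test_that("Y-maze policies hit their analytic alternation levels", {
  expect_equal(alternationIndex(generateYmazeSession("alternating", 12,
                                                     seed = 1)), 100)
  # random policy: each triplet is distinct with probability exactly 1/2
  # (the third entry picks uniformly between 2 arms, one of which closes
  # a distinct triplet), so the exact chance level is 50%
  idx <- vapply(1:400, function(s)
    alternationIndex(generateYmazeSession("random", 15, seed = s)),
    numeric(1))
  se <- sd(idx) / sqrt(400)
  expect_lt(abs(mean(idx) - 50), 3 * se)
})

test_that("%PPI is the fractional startle reduction per intensity", {
  tab <- data.frame(
    trialType = c(rep("pulse_alone", 2), rep("prepulse", 4)),
    intensity = c(NA, NA, 74, 74, 78, 78),
    amplitude = c(100, 100, 40, 40, 120, 120))
  out <- ppiPercent(tab)
  expect_equal(out$ppi[out$intensity == 74], 60)
  expect_equal(out$ppi[out$intensity == 78], -20)   # facilitation, unclipped
  eq <- tab; eq$amplitude <- 100
  expect_true(all(ppiPercent(eq)$ppi == 0))
  # invariant under multiplicative rescaling of all amplitudes
  sc <- tab; sc$amplitude <- tab$amplitude * 7.7
  expect_equal(ppiPercent(sc)$ppi, out$ppi)
  bad <- tab; bad$amplitude[bad$trialType == "pulse_alone"] <- 0
  expect_error(ppiPercent(bad), "zero")
})

test_that("PPI sessions recover the preset attenuation; startle is condition-free", {
  ctrl <- makePreset("control")
  noiseless <- ppiPercent(generatePpiSession(ctrl, noiseSdLog = 0, seed = 1))
  expect_equal(noiseless$ppi, unname(100 * ctrl@ppiAttenuation))
  # control PPI exceeds mutant PPI at every intensity; pulse-alone startle
  # has the same distribution in both conditions
  mut <- makePreset("mutant")
  pc <- ppiPercent(generatePpiSession(ctrl, seed = 2))
  pm <- ppiPercent(generatePpiSession(mut, seed = 2))
  expect_true(all(pc$ppi > pm$ppi))
  expect_equal(attr(pc, "pulseAloneMean"), attr(pm, "pulseAloneMean"))
})
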