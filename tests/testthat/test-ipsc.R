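test_that("detection applies the strict > 5 pA rule", {
  tr <- eventTrainsFixture(c(1, 2, 3), 1, duration = 5, ampsA = c(8, 6, 4))
  rd <- renderIpscTraces(tr, sampleRate = 10000)
  ev <- detectIpscEvents(rd$traceA, rd$sampleRate)
  expect_identical(nrow(ev), 2L)                # the 4-pA event is below cut
  expect_equal(sort(ev$amplitude), c(6, 8), tolerance = 0.05)
  # exactly 5.0 pA is excluded; 5.05 is kept
  tr5 <- eventTrainsFixture(1, 1, 3, ampsA = 5)
  expect_identical(nrow(detectIpscEvents(
    renderIpscTraces(tr5, 10000)$traceA, 10000)), 0L)
  tr51 <- eventTrainsFixture(1, 1, 3, ampsA = 5.05)
  expect_identical(nrow(detectIpscEvents(
    renderIpscTraces(tr51, 10000)$traceA, 10000)), 1L)
  # flat trace: empty result, not an error
  expect_identical(nrow(detectIpscEvents(rep(0, 20000), 10000)), 0L)
  expect_error(detectIpscEvents(rep(0, 100), 1000), "2 kHz")
})

test_that("rendering: unit-peak kernel, noise-free peak location, rate guard", {
  tr <- eventTrainsFixture(1, 1, 3, ampsA = 20)
  rd <- renderIpscTraces(tr, sampleRate = 10000)
  expect_equal(max(rd$traceA), 20, tolerance = 1e-9)
  expect_equal((which.max(rd$traceA) - 1) / 1e4, 1 + rd$peakDelay,
               tolerance = 2e-4)
  empty <- eventTrainsFixture(numeric(0), 1, 3)
  expect_equal(max(abs(renderIpscTraces(empty, 10000)$traceA)), 0)
  expect_error(renderIpscTraces(tr, sampleRate = 2000), "rise")
  expect_error(renderIpscTraces(tr, riseTau = 0.01, decayTau = 0.005),
               "decayTau")
})

test_that("detector recovers >= 95% of rendered events within 2 ms at 1 pA noise", {
  set.seed(21)
  n <- 100
  times <- sort(runif(n, 0.5, 59.5))
  times <- times[c(TRUE, diff(times) > 0.01)]
  tr <- eventTrainsFixture(times, 1, 60,
                           ampsA = runif(length(times), 10, 40))
  # oracle: the detector on the noise-free render finds every event
  clean <- renderIpscTraces(tr, 10000)
  evClean <- detectIpscEvents(clean$traceA, 10000)
  expect_identical(nrow(evClean), length(times))
  noisy <- renderIpscTraces(tr, 10000, noiseSd = 1, seed = 22)
  ev <- detectIpscEvents(noisy$traceA, 10000)
  matched <- vapply(times + clean$peakDelay,
                    function(t0) any(abs(ev$time - t0) <= 0.002), logical(1))
  expect_gte(sum(matched), ceiling(0.95 * length(times)))
})

test_that("synchronous fraction honours the closed +/-10 ms window", {
  t <- c(1, 2.5, 4, 7)
  expect_equal(synchronousFraction(eventTrainsFixture(t, t, 10))@pctSynchronous,
               100)
  off <- eventTrainsFixture(t, t + 0.015, 10)        # 15 ms > 10 ms
  expect_equal(synchronousFraction(off)@pctSynchronous, 0)
  edge <- eventTrainsFixture(1, 1.010, 10)           # exactly on the bound
  expect_equal(synchronousFraction(edge)@pctSynchronous, 100)
  expect_warning(
    s0 <- synchronousFraction(eventTrainsFixture(numeric(0), t, 10)), "empty")
  expect_equal(s0@pctSynchronous, 0)
})

test_that("synchronous fraction is symmetric and monotone in the window", {
  tr <- generateEventTrainPair(2.5, 0.5, 120, seed = 31)
  swap <- eventTrainsFixture(timesB(tr), timesA(tr), 120,
                             ampsA = amplitudesB(tr), ampsB = amplitudesA(tr))
  expect_equal(synchronousFraction(tr)@pctSynchronous,
               synchronousFraction(swap)@pctSynchronous)
  ws <- c(0.002, 0.005, 0.01, 0.02, 0.05)
  pcts <- vapply(ws, function(w)
    synchronousFraction(tr, w)@pctSynchronous, numeric(1))
  expect_true(all(diff(pcts) >= 0))
})

test_that("Poisson mixtures match the closed-form coincidence expectation", {
  grid <- list(c(1, 0.2), c(2, 0.5), c(3.5, 0.6), c(5, 1))  # (total, shared)
  for (g in grid) {
    r <- g[1]; s <- g[2]
    pcts <- vapply(1:20, function(k)
      synchronousFraction(generateEventTrainPair(r - s, s, 200,
                                                 seed = 5000 + k))@pctSynchronous,
      numeric(1))
    se <- sd(pcts) / sqrt(20)
    expect_lt(abs(mean(pcts) - expectedSynchronousPct(r, s)), 3 * se + 0.05)
  }
})

test_that("render -> detect -> coincidence reproduces train-level synchrony", {
  tp <- generateEventTrainPair(2.848, 0.645, 60, seed = 9)
  rr <- renderIpscTraces(tp, 10000, noiseSd = 1, seed = 10)
  ea <- detectIpscEvents(rr$traceA, 1e4)
  eb <- detectIpscEvents(rr$traceB, 1e4)
  det <- eventTrainsFixture(ea$time, eb$time, 60,
                            ampsA = ea$amplitude, ampsB = eb$amplitude)
  expect_lt(abs(synchronousFraction(det)@pctSynchronous -
                synchronousFraction(tp)@pctSynchronous), 2)
})

test_that("inter-event intervals summarize successive differences", {
  r <- interEventIntervals(c(0, 0.3, 0.6))
  expect_equal(r$mean, 0.3)
  expect_identical(r$n, 2L)
  expect_error(interEventIntervals(0.5), "at least 2")
  # reversal leaves the interval multiset unchanged
  set.seed(12)
  t <- sort(runif(50, 0, 30))
  rev <- sort(30 - t)
  expect_equal(sort(interEventIntervals(t)$intervals),
               sort(interEventIntervals(rev)$intervals), tolerance = 1e-12)
  # Poisson train at 2.331 Hz: mean IEI ~ 1/rate = 429 ms
  tr <- generateEventTrainPair(2.331, 0, 600, seed = 3)
  expect_equal(1000 * interEventIntervals(tr)$grandMean, 1000 / 2.331,
               tolerance = 0.05)
})
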