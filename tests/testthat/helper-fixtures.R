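# Fixture builders: everything is generated in code at test time.

# Build a valid LFPTrialSet around a given trial matrix.  Defaults supply a
# non-flat pre-stimulus record and zero mid-ISI segments.
lfpFixture <- function(trialMat, fs = 500, midIsi = NULL, prestim = NULL,
                       window = c(-0.5, 1.0), normalized = FALSE) {
  nT <- nrow(trialMat)
  if (is.null(midIsi)) midIsi <- matrix(0, nT, round(0.2 * fs))
  if (is.null(prestim))
    prestim <- sin(2 * pi * 7 * seq_len(round(10 * fs)) / fs)
  new("LFPTrialSet", sampleRate = fs, trials = trialMat,
      midIsiSegments = midIsi, prestimRecord = prestim,
      trialWindow = window, stimOnsets = 10 + (seq_len(nT) - 1) * 20,
      subjectId = "s1", channelId = "ch1", normalized = normalized)
}

# One trial row over the standard window: 40-Hz sinusoid of amplitude A
# and phase phi during the 500-ms stimulus, zero elsewhere.
sineTrial <- function(fs = 500, A = 1, phi = 0, f = 40,
                      window = c(-0.5, 1.0)) {
  tt <- window[1] + (seq_len(round(diff(window) * fs)) - 1) / fs
  out <- numeric(length(tt))
  on <- tt >= 0 & tt < 0.5
  out[on] <- A * cos(2 * pi * f * tt[on] + phi)
  out
}

# Preset modified field-by-field (for controlled generator experiments).
presetWith <- function(label = "control", ...) {
  p <- makePreset(label)
  mods <- list(...)
  for (nm in names(mods)) slot(p, nm) <- mods[[nm]]
  p
}

spikePairFixture <- function(timesA, timesB, duration) {
  new("SpikeTrainPair", timesA = timesA, timesB = timesB,
      duration = duration, unitIds = c("u1", "u2"))
}

eventTrainsFixture <- function(timesA, timesB, duration,
                               ampsA = rep(20, length(timesA)),
                               ampsB = rep(20, length(timesB))) {
  new("IPSCEventTrains", timesA = timesA, timesB = timesB,
      ampsA = ampsA, ampsB = ampsB, duration = duration)
}
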