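#' Accessors for gammasynch data classes
#'
#' Slot accessors for the package's S4 containers; use these rather than
#' \code{@} access.
#'
#' @param x a gammasynch data object.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
setMethod("sampleRate", "LFPTrialSet", function(x) x@sampleRate)
#' @rdname accessors
setMethod("trials", "LFPTrialSet", function(x) x@trials)
#' @rdname accessors
setMethod("midIsiSegments", "LFPTrialSet", function(x) x@midIsiSegments)
#' @rdname accessors
setMethod("prestimRecord", "LFPTrialSet", function(x) x@prestimRecord)
#' @rdname accessors
setMethod("trialWindow", "LFPTrialSet", function(x) x@trialWindow)
#' @rdname accessors
setMethod("subjectId", "LFPTrialSet", function(x) x@subjectId)
#' @rdname accessors
setMethod("channelId", "LFPTrialSet", function(x) x@channelId)
#' @rdname accessors
setMethod("isNormalized", "LFPTrialSet", function(x) x@normalized)

#' @rdname accessors
setMethod("presetLabel", "GenotypePreset", function(x) x@label)

#' @rdname accessors
setMethod("timesA", "SpikeTrainPair", function(x) x@timesA)
#' @rdname accessors
setMethod("timesB", "SpikeTrainPair", function(x) x@timesB)
#' @rdname accessors
setMethod("recordingDuration", "SpikeTrainPair", function(x) x@duration)

#' @rdname accessors
setMethod("timesA", "IPSCEventTrains", function(x) x@timesA)
#' @rdname accessors
setMethod("timesB", "IPSCEventTrains", function(x) x@timesB)
#' @rdname accessors
setMethod("amplitudesA", "IPSCEventTrains", function(x) x@ampsA)
#' @rdname accessors
setMethod("amplitudesB", "IPSCEventTrains", function(x) x@ampsB)
#' @rdname accessors
setMethod("recordingDuration", "IPSCEventTrains", function(x) x@duration)

#' @rdname accessors
setMethod("armEntries", "YMazeSession", function(x) x@entries)
#' @rdname accessors
setMethod("startleTrials", "StartleSession", function(x) x@trials)

#' @rdname accessors
setMethod("specPower", "Spectrogram", function(x) {
  p <- Mod(x@values)^2
  dimnames(p) <- dimnames(x@values)
  p
})

setMethod("show", "GenotypePreset", function(object) {
  cat("GenotypePreset '", object@label, "'\n", sep = "")
  cat(sprintf("  evoked 40-Hz amp: %g uV (phase kappa %g)\n",
              object@evokedAmp, object@phaseKappa))
  cat(sprintf("  baseline gamma amp: %g uV; N1 depth: %g uV; pink noise sd: %g uV\n",
              object@baselineGammaAmp, object@n1Amp, object@pinkNoiseSd))
  cat(sprintf("  sIPSC rates: %g Hz independent + %g Hz shared\n",
              object@ipscIndepRate, object@ipscSharedRate))
  cat(sprintf("  spikes: %g Hz, shared fraction %g\n",
              object@spikeRate, object@spikeSharedFrac))
  cat(sprintf("  behaviour: alternation lapse %g; PPI attenuation %s\n",
              object@alternationLapse,
              paste(sprintf("%s dB: %.2f", names(object@ppiAttenuation),
                            object@ppiAttenuation), collapse = ", ")))
})

setMethod("show", "LFPTrialSet", function(object) {
  cat(sprintf(
    "LFPTrialSet: %d trials x %d samples @ %g Hz (%s)\n",
    nrow(object@trials), ncol(object@trials), object@sampleRate,
    if (object@normalized) "z-scored" else "raw uV"))
  cat(sprintf("  window [%g, %g] s; %d mid-ISI segments; prestim %.1f s\n",
              object@trialWindow[1], object@trialWindow[2],
              nrow(object@midIsiSegments),
              length(object@prestimRecord) / object@sampleRate))
  cat(sprintf("  subject %s, channel %s\n", object@subjectId, object@channelId))
})

setMethod("show", "SpikeTrainPair", function(object) {
  cat(sprintf("SpikeTrainPair: %d + %d spikes over %g s (units %s, %s)\n",
              length(object@timesA), length(object@timesB), object@duration,
              object@unitIds[1], object@unitIds[2]))
})

setMethod("show", "IPSCEventTrains", function(object) {
  cat(sprintf("IPSCEventTrains: %d + %d events over %g s\n",
              length(object@timesA), length(object@timesB), object@duration))
})

setMethod("show", "Spectrogram", function(object) {
  cat(sprintf("Spectrogram (%s): %d freqs [%g, %g] Hz x %d times\n",
              object@method, length(object@freqs), min(object@freqs),
              max(object@freqs), length(object@times)))
})

setMethod("show", "ITCMatrix", function(object) {
  cat(sprintf("ITCMatrix: %d freqs x %d times, %d trials\n",
              length(object@freqs), length(object@times), object@nTrials))
  cat(sprintf("  band metric (%g-%g Hz, [%g, %g] s): %.3f\n",
              object@band[1], object@band[2], object@window[1],
              object@window[2], object@bandMetric))
})

setMethod("show", "CrossCorrResult", function(object) {
  cat(sprintf("CrossCorrResult: zero-lag r = %.4f (%g-ms bins, %d bins)\n",
              object@coefficient, object@binWidth * 1000, object@nBins))
  if (!is.na(object@nullMean))
    cat(sprintf("  shuffle null: mean %.4f, sd %.4f, observed quantile %.3f\n",
                object@nullMean, object@nullSd, object@nullQuantile))
})

setMethod("show", "SynchronyResult", function(object) {
  cat(sprintf("SynchronyResult: %.2f%% synchronous (+/-%g ms window)\n",
              object@pctSynchronous, object@windowHalfwidth * 1000))
  cat(sprintf("  events: %d (A) / %d (B); mean IEI: %.1f / %.1f ms\n",
              object@nEventsA, object@nEventsB,
              object@meanIeiA * 1000, object@meanIeiB * 1000))
})
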