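#' @import methods
NULL

#' Condition preset for the synthetic-data generators
#'
#' A frozen bundle of simulator parameters keyed by a condition label.  The
#' fields control every generator in the package: the stimulus-entrained
#' 40-Hz component of the LFP (\code{evokedAmp}, with per-trial phase
#' concentration \code{phaseKappa}), the ongoing 35--44 Hz background
#' (\code{baselineGammaAmp}), the onset ERP (\code{n1Amp}), broadband
#' 1/f noise (\code{pinkNoiseSd}), paired sIPSC event rates
#' (\code{ipscIndepRate}, \code{ipscSharedRate}), spike-pair structure
#' (\code{spikeRate}, \code{spikeSharedFrac}) and behaviour
#' (\code{alternationLapse}, \code{ppiAttenuation}).
#'
#' @slot label condition label, e.g. \code{"control"} or \code{"mutant"}.
#' @slot evokedAmp amplitude (uV) of the stimulus-entrained 40-Hz sinusoid.
#' @slot phaseKappa von Mises concentration of the per-trial evoked phase;
#'   0 gives uniform phase (no intertrial coherence), large values give
#'   near-perfect phase locking.
#' @slot baselineGammaAmp amplitude (uV) of the ongoing 35--44 Hz band
#'   process, present throughout the recording.
#' @slot n1Amp depth (uV) of the negative onset deflection (N1).
#' @slot pinkNoiseSd standard deviation (uV) of the broadband 1/f noise.
#' @slot ipscIndepRate per-cell independent sIPSC event rate (Hz).
#' @slot ipscSharedRate rate (Hz) of sIPSC events shared by both cells of a
#'   pair.
#' @slot spikeRate marginal firing rate (Hz) of each unit of a spike pair.
#' @slot spikeSharedFrac fraction of each unit's spikes that are shared
#'   (zero-lag common input); equals the expected zero-lag count
#'   correlation at fine bins.
#' @slot alternationLapse probability that a Y-maze arm choice is random
#'   rather than the least recently visited arm.
#' @slot ppiAttenuation named numeric vector of fractional startle
#'   reductions per prepulse intensity (names are intensities in dB).
#'
#' @seealso [makePreset()], [presetTable()]
#' @export
setClass("GenotypePreset",
  representation(
    label = "character",
    evokedAmp = "numeric",
    phaseKappa = "numeric",
    baselineGammaAmp = "numeric",
    n1Amp = "numeric",
    pinkNoiseSd = "numeric",
    ipscIndepRate = "numeric",
    ipscSharedRate = "numeric",
    spikeRate = "numeric",
    spikeSharedFrac = "numeric",
    alternationLapse = "numeric",
    ppiAttenuation = "numeric"
  )
)

setValidity("GenotypePreset", function(object) {
  msg <- character(0)
  nonneg <- c(
    evokedAmp = object@evokedAmp, baselineGammaAmp = object@baselineGammaAmp,
    n1Amp = object@n1Amp, pinkNoiseSd = object@pinkNoiseSd,
    ipscIndepRate = object@ipscIndepRate,
    ipscSharedRate = object@ipscSharedRate, spikeRate = object@spikeRate
  )
  if (any(nonneg < 0))
    msg <- c(msg, paste("negative parameter:",
                        paste(names(nonneg)[nonneg < 0], collapse = ", ")))
  if (object@phaseKappa < 0) msg <- c(msg, "phaseKappa must be >= 0")
  if (object@spikeSharedFrac < 0 || object@spikeSharedFrac > 1)
    msg <- c(msg, "spikeSharedFrac must lie in [0, 1]")
  if (object@alternationLapse < 0 || object@alternationLapse > 1)
    msg <- c(msg, "alternationLapse must lie in [0, 1]")
  if (any(object@ppiAttenuation > 1))
    msg <- c(msg, "ppiAttenuation must be <= 1")
  if (length(msg)) msg else TRUE
})

#' Trial-structured local field potential recording
#'
#' Holds the LFP segments an auditory steady-state response (ASSR) analysis
#' needs: one trial per click train (aligned to train onset, covering
#' \code{trialWindow}), a 200-ms spontaneous segment taken at the mid-point
#' of the inter-stimulus interval preceding each trial, and a continuous
#' pre-stimulus record of at least 10 s preceding the first train (used for
#' z-scoring and baseline band power).
#'
#' @slot sampleRate sampling rate in Hz (shared by all segments).
#' @slot trials numeric matrix, trials x samples, in uV (or z units once
#'   normalized); each row covers \code{trialWindow} around train onset.
#' @slot midIsiSegments numeric matrix, trials x samples, 200-ms spontaneous
#'   segments at the mid-point of each preceding ISI.
#' @slot prestimRecord numeric vector, >= 10 s of LFP before the first train.
#' @slot trialWindow length-2 numeric, seconds relative to train onset
#'   spanned by each trial row (default c(-0.5, 1.0)).
#' @slot stimOnsets train onset times (s) in session time.
#' @slot subjectId,channelId identifiers used by aggregation.
#' @slot normalized logical; TRUE once [zscoreLfp()] has been applied.
#' @export
setClass("LFPTrialSet",
  representation(
    sampleRate = "numeric",
    trials = "matrix",
    midIsiSegments = "matrix",
    prestimRecord = "numeric",
    trialWindow = "numeric",
    stimOnsets = "numeric",
    subjectId = "character",
    channelId = "character",
    normalized = "logical"
  )
)

setValidity("LFPTrialSet", function(object) {
  msg <- character(0)
  fs <- object@sampleRate
  if (length(fs) != 1 || fs <= 0) msg <- c(msg, "sampleRate must be a positive scalar")
  if (nrow(object@trials) < 1) msg <- c(msg, "at least one trial required")
  if (length(object@trialWindow) != 2 || diff(object@trialWindow) <= 0)
    msg <- c(msg, "trialWindow must be an increasing length-2 vector")
  if (length(fs) == 1 && fs > 0) {
    if (ncol(object@trials) != round(diff(object@trialWindow) * fs))
      msg <- c(msg, "trial length inconsistent with trialWindow and sampleRate")
    if (nrow(object@midIsiSegments) > 0 &&
        ncol(object@midIsiSegments) != round(0.2 * fs))
      msg <- c(msg, "mid-ISI segments must be 200 ms long")
    if (length(object@prestimRecord) < round(10 * fs))
      msg <- c(msg, "prestimRecord must cover at least 10 s")
  }
  if (nrow(object@midIsiSegments) > 0 &&
      nrow(object@midIsiSegments) != nrow(object@trials))
    msg <- c(msg, "need one mid-ISI segment per trial")
  if (length(msg)) msg else TRUE
})

#' Pair of sorted spike trains from one tetrode
#'
#' @slot timesA,timesB strictly sorted spike times (s) in [0, duration].
#' @slot duration session duration (s).
#' @slot unitIds length-2 character vector of unit identifiers.
#' @export
setClass("SpikeTrainPair",
  representation(timesA = "numeric", timesB = "numeric",
                 duration = "numeric", unitIds = "character")
)

setValidity("SpikeTrainPair", function(object) {
  msg <- character(0)
  if (length(object@duration) != 1 || object@duration <= 0)
    msg <- c(msg, "duration must be a positive scalar")
  for (nm in c("timesA", "timesB")) {
    t <- slot(object, nm)
    if (is.unsorted(t, strictly = TRUE)) msg <- c(msg, paste(nm, "must be strictly sorted"))
    if (length(t) && (min(t) < 0 || max(t) > object@duration))
      msg <- c(msg, paste(nm, "must lie within [0, duration]"))
  }
  if (length(msg)) msg else TRUE
})

#' Paired sIPSC event trains with per-event amplitudes
#'
#' Event times and amplitudes for a simultaneously recorded pyramidal-cell
#' pair, the substrate of the synchronous-GABA-release analysis.
#'
#' @slot timesA,timesB sorted event times (s).
#' @slot ampsA,ampsB per-event amplitudes (pA), strictly positive.
#' @slot duration recording duration (s).
#' @export
setClass("IPSCEventTrains",
  representation(timesA = "numeric", timesB = "numeric",
                 ampsA = "numeric", ampsB = "numeric", duration = "numeric")
)

setValidity("IPSCEventTrains", function(object) {
  msg <- character(0)
  if (length(object@duration) != 1 || object@duration <= 0)
    msg <- c(msg, "duration must be a positive scalar")
  if (length(object@timesA) != length(object@ampsA) ||
      length(object@timesB) != length(object@ampsB))
    msg <- c(msg, "each event needs an amplitude")
  if (is.unsorted(object@timesA) || is.unsorted(object@timesB))
    msg <- c(msg, "event times must be sorted")
  if (any(c(object@ampsA, object@ampsB) <= 0))
    msg <- c(msg, "amplitudes must be > 0")
  if (length(msg)) msg else TRUE
})

#' Y-maze session: sequence of arm entries
#'
#' @slot entries character vector over \{"A","B","C"\}; consecutive entries
#'   differ (an entry is a transition between arms).
#' @export
setClass("YMazeSession", representation(entries = "character"))

setValidity("YMazeSession", function(object) {
  e <- object@entries
  msg <- character(0)
  if (!all(e %in% c("A", "B", "C"))) msg <- c(msg, "entries must be in {A,B,C}")
  if (length(e) >= 2 && any(e[-1] == e[-length(e)]))
    msg <- c(msg, "consecutive entries must differ")
  if (length(msg)) msg else TRUE
})

#' Acoustic startle session: per-trial startle amplitudes
#'
#' @slot trials data.frame with columns \code{trialType}
#'   ("pulse_alone" or "prepulse"), \code{intensity} (prepulse intensity in
#'   dB, NA for pulse-alone trials) and \code{amplitude} (a.u., >= 0).
#' @export
setClass("StartleSession", representation(trials = "data.frame"))

setValidity("StartleSession", function(object) {
  d <- object@trials
  msg <- character(0)
  need <- c("trialType", "intensity", "amplitude")
  if (!all(need %in% names(d))) {
    msg <- c(msg, paste("trials must have columns:", paste(need, collapse = ", ")))
  } else {
    if (any(d$amplitude < 0)) msg <- c(msg, "amplitudes must be >= 0")
    if (!all(d$trialType %in% c("pulse_alone", "prepulse")))
      msg <- c(msg, "trialType must be 'pulse_alone' or 'prepulse'")
  }
  if (length(msg)) msg else TRUE
})

#' Time-frequency decomposition of a single trace
#'
#' @slot freqs frequency grid (Hz).
#' @slot times time grid (s), in the trace's own time base.
#' @slot values complex coefficient matrix, freqs x times; power is
#'   \code{Mod(values)^2}.
#' @slot method "morlet" or "stft".
#' @slot sampleRate sampling rate (Hz) of the decomposed trace.
#' @export
setClass("Spectrogram",
  representation(freqs = "numeric", times = "numeric", values = "matrix",
                 method = "character", sampleRate = "numeric")
)

setValidity("Spectrogram", function(object) {
  msg <- character(0)
  if (nrow(object@values) != length(object@freqs) ||
      ncol(object@values) != length(object@times))
    msg <- c(msg, "values must be freqs x times")
  if (length(msg)) msg else TRUE
})

#' Intertrial coherence matrix
#'
#' ITC(f, t) is the resultant length of the per-trial spectral phases:
#' 0 for random phase, 1 for perfect locking.  Bins where the spectral
#' power of some trial vanishes have no defined phase; they are excluded
#' (NA) and flagged in \code{excluded}.
#'
#' @slot freqs,times grids as in [Spectrogram-class].
#' @slot values ITC in [0, 1] (NA where excluded).
#' @slot excluded logical matrix flagging zero-power bins.
#' @slot nTrials number of trials entering the average.
#' @slot bandMetric mean ITC over the summary band and window.
#' @slot band,window the band (Hz) and window (s) of \code{bandMetric}.
#' @export
setClass("ITCMatrix",
  representation(freqs = "numeric", times = "numeric", values = "matrix",
                 excluded = "matrix", nTrials = "numeric",
                 bandMetric = "numeric", band = "numeric", window = "numeric")
)

setValidity("ITCMatrix", function(object) {
  v <- object@values[!object@excluded]
  msg <- character(0)
  if (length(v) && (min(v, na.rm = TRUE) < -1e-9 || max(v, na.rm = TRUE) > 1 + 1e-9))
    msg <- c(msg, "ITC values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Spike-pair cross-correlation result
#'
#' @slot coefficient zero-lag Pearson r of binned counts (NA if a count
#'   vector has zero variance).
#' @slot correlogram data.frame(lag, r) over integer-bin lags to +/- maxLag.
#' @slot binWidth bin width (s).
#' @slot nBins number of bins used.
#' @slot nullMean,nullSd,nullQuantile shuffle-null summaries (NA until
#'   [shuffleNull()] is applied).
#' @export
setClass("CrossCorrResult",
  representation(coefficient = "numeric", correlogram = "data.frame",
                 binWidth = "numeric", nBins = "numeric",
                 nullMean = "numeric", nullSd = "numeric",
                 nullQuantile = "numeric")
)

#' Synchronous sIPSC summary for one cell pair
#'
#' @slot pctSynchronous percentage of pooled events (both cells) with at
#'   least one partner event in the other cell within the coincidence
#'   window.
#' @slot perCellPct named vector: the same percentage computed per cell.
#' @slot windowHalfwidth coincidence half-width (s), default 0.010.
#' @slot nEventsA,nEventsB event counts.
#' @slot meanIeiA,meanIeiB mean inter-event interval (s) per cell (NA with
#'   fewer than 2 events).
#' @export
setClass("SynchronyResult",
  representation(pctSynchronous = "numeric", perCellPct = "numeric",
                 windowHalfwidth = "numeric",
                 nEventsA = "numeric", nEventsB = "numeric",
                 meanIeiA = "numeric", meanIeiB = "numeric")
)

setValidity("SynchronyResult", function(object) {
  msg <- character(0)
  if (object@windowHalfwidth <= 0) msg <- c(msg, "windowHalfwidth must be > 0")
  if (object@pctSynchronous < 0 || object@pctSynchronous > 100)
    msg <- c(msg, "pctSynchronous must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})
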