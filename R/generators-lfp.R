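#' Generate trial-structured ASSR LFP data
#'
#' Simulates the LFP of one recording channel during a 40-Hz click-train
#' session: \code{nTrials} trains of 500 ms presented with a 20-s
#' inter-stimulus interval, preceded by a 10-s spontaneous record.  Each
#' trial trace is the sum of
#' \itemize{
#'   \item pink (1/f) broadband noise with sd \code{pinkNoiseSd},
#'   \item an ongoing narrow-band 35--44 Hz process of amplitude
#'     \code{baselineGammaAmp}, present in every segment (trials, mid-ISI
#'     segments and the pre-stimulus record),
#'   \item during the 500-ms stimulus, a 40-Hz sinusoid of amplitude
#'     \code{evokedAmp} whose per-trial phase is von Mises distributed
#'     around 0 with concentration \code{phaseKappa}; its envelope ramps
#'     up quadratically over the first 150 ms, emulating the build-up of
#'     steady-state entrainment over the first few cycles (full amplitude
#'     well before the 300--500 ms analysis window), and
#'   \item a negative Gaussian-shaped onset deflection (N1) of depth
#'     \code{n1Amp}, centred 40 ms post-onset with 25-ms full width at
#'     half maximum.
#' }
#' A 200-ms spontaneous segment at the mid-point of each preceding ISI is
#' stored alongside each trial, as required by the spontaneous-power
#' subtraction in [assrPower()].
#'
#' @param preset a [GenotypePreset-class] from [makePreset()].
#' @param nTrials number of click trains (default 50).
#' @param sampleRate sampling rate in Hz (>= 500; default 1000).
#' @param seed integer seed; identical (preset, seed) give bit-identical
#'   output.
#' @param subjectId,channelId identifiers carried into metric tables.
#' @return an [LFPTrialSet-class] (raw uV; apply [zscoreLfp()] before the
#'   power analyses).
#' @examples
#' x <- generateAssrTrials(makePreset("control"), nTrials = 5, seed = 1)
#' x
#' @export
generateAssrTrials <- function(preset, nTrials = 50, sampleRate = 1000,
                               seed = NULL, subjectId = "s1",
                               channelId = "ch1") {
  stopifnot(is(preset, "GenotypePreset"))
  if (nTrials < 1) stop("nTrials must be >= 1")
  if (sampleRate < 500) stop("sampleRate must be >= 500 Hz")
  win <- c(-0.5, 1.0)
  nSamp <- round(diff(win) * sampleRate)
  nMid <- round(0.2 * sampleRate)
  nPre <- round(10 * sampleRate)
  tTrial <- win[1] + (seq_len(nSamp) - 1) / sampleRate
  stimIdx <- tTrial >= 0 & tTrial < 0.5
  n1Sigma <- 0.025 / (2 * sqrt(2 * log(2)))    # 25-ms FWHM
  n1Shape <- exp(-(tTrial - 0.040)^2 / (2 * n1Sigma^2))
  # steady-state entrainment builds up over the first ~6 cycles; the ramp
  # reaches full amplitude by 150 ms, well before the 300-500 ms analysis
  # window, and keeps the onset ERP (N1) separable from the entrained
  # oscillation
  rampEnv <- pmin(1, (tTrial[stimIdx] / 0.15)^2)

  withSeed(seed, {
    phases <- rVonMises(nTrials, 0, preset@phaseKappa)
    trials <- matrix(0, nTrials, nSamp)
    midIsi <- matrix(0, nTrials, nMid)
    for (i in seq_len(nTrials)) {
      tr <- pinkNoise(nSamp, preset@pinkNoiseSd) +
        narrowbandNoise(nSamp, sampleRate, c(35, 44), preset@baselineGammaAmp)
      tr[stimIdx] <- tr[stimIdx] +
        preset@evokedAmp * rampEnv *
          cos(2 * pi * 40 * tTrial[stimIdx] + phases[i])
      tr <- tr - preset@n1Amp * n1Shape
      trials[i, ] <- tr
      midIsi[i, ] <- pinkNoise(nMid, preset@pinkNoiseSd) +
        narrowbandNoise(nMid, sampleRate, c(35, 44), preset@baselineGammaAmp)
    }
    prestim <- pinkNoise(nPre, preset@pinkNoiseSd) +
      narrowbandNoise(nPre, sampleRate, c(35, 44), preset@baselineGammaAmp)
    new("LFPTrialSet", sampleRate = sampleRate, trials = trials,
        midIsiSegments = midIsi, prestimRecord = prestim,
        trialWindow = win, stimOnsets = 10 + (seq_len(nTrials) - 1) * 20,
        subjectId = subjectId, channelId = channelId, normalized = FALSE)
  })
}
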