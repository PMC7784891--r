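# Condition presets: the one versioned table of simulator parameters.
#
# The mutant condition carries the full phenotype relative to control:
# lower evoked 40-Hz amplitude and phase concentration, elevated baseline
# gamma, smaller N1, sparser and less-shared sIPSC events, weaker spike
# sharing, chance-level alternation and reduced PPI.  The GSK3B-inhibited
# and GSK3B-knockdown presets equal control on every field except the N1
# depth, which stays at the mutant level (the inhibitor normalizes the
# oscillatory and behavioural phenotype but not the N1).  The
# GSK3A-inhibited preset equals the mutant (no rescue).
#
# sIPSC rates for control and mutant are calibrated so that the total
# per-cell rates (3.493 and 2.331 Hz) give mean inter-event intervals of
# 286.3 and 429.0 ms, and the shared rates give the reported synchronous
# percentages under the +/-10 ms rule.

.presetParams <- list(
  control = list(
    evokedAmp = 25, phaseKappa = 6, baselineGammaAmp = 6, n1Amp = 40,
    pinkNoiseSd = 15, ipscIndepRate = 2.848, ipscSharedRate = 0.645,
    spikeRate = 6, spikeSharedFrac = 0.30, alternationLapse = 0.60,
    ppiAttenuation = c("74" = 0.35, "78" = 0.50, "82" = 0.65)
  ),
  mutant = list(
    evokedAmp = 8, phaseKappa = 1.2, baselineGammaAmp = 12, n1Amp = 20,
    pinkNoiseSd = 15, ipscIndepRate = 2.151, ipscSharedRate = 0.180,
    spikeRate = 6, spikeSharedFrac = 0.08, alternationLapse = 1.00,
    ppiAttenuation = c("74" = 0.10, "78" = 0.18, "82" = 0.25)
  )
)
.presetParams$mutant_gsk3b_inhibited <- within(.presetParams$control, {
  n1Amp <- .presetParams$mutant$n1Amp
})
.presetParams$mutant_gsk3b_knockdown <- .presetParams$mutant_gsk3b_inhibited
.presetParams$mutant_gsk3a_inhibited <- .presetParams$mutant

#' Registered condition labels
#' @return character vector of labels accepted by [makePreset()].
#' @export
presetLabels <- function() names(.presetParams)

#' Build a condition preset
#'
#' Returns the frozen simulator parameter bundle for one registered
#' condition.  The presets encode the qualitative condition contrasts the
#' analyses are expected to recover: relative to \code{"control"}, the
#' \code{"mutant"} preset has lower evoked 40-Hz amplitude and phase
#' concentration, higher baseline gamma, lower N1, sparser and less-shared
#' sIPSC events, weaker spike sharing, chance-level alternation and reduced
#' prepulse inhibition.  \code{"mutant_gsk3b_inhibited"} and
#' \code{"mutant_gsk3b_knockdown"} equal control except for the N1 depth,
#' which remains at the mutant level; \code{"mutant_gsk3a_inhibited"}
#' equals the mutant (no rescue).
#'
#' @param label one of [presetLabels()].
#' @return a [GenotypePreset-class] object.
#' @examples
#' makePreset("control")
#' @export
makePreset <- function(label) {
  if (!is.character(label) || length(label) != 1 || !label %in% names(.presetParams))
    stop("unknown preset label ", deparse(label), "; registered labels: ",
         paste(names(.presetParams), collapse = ", "))
  p <- .presetParams[[label]]
  new("GenotypePreset", label = label,
      evokedAmp = p$evokedAmp, phaseKappa = p$phaseKappa,
      baselineGammaAmp = p$baselineGammaAmp, n1Amp = p$n1Amp,
      pinkNoiseSd = p$pinkNoiseSd, ipscIndepRate = p$ipscIndepRate,
      ipscSharedRate = p$ipscSharedRate, spikeRate = p$spikeRate,
      spikeSharedFrac = p$spikeSharedFrac,
      alternationLapse = p$alternationLapse,
      ppiAttenuation = p$ppiAttenuation)
}

#' Preset parameter table
#'
#' The simulator parameters of all registered presets in one data frame
#' (one row per preset), so the calibration lives in a single place.
#'
#' @return data.frame with one row per preset label.
#' @export
presetTable <- function() {
  rows <- lapply(names(.presetParams), function(lbl) {
    p <- .presetParams[[lbl]]
    data.frame(label = lbl, evokedAmp = p$evokedAmp,
               phaseKappa = p$phaseKappa,
               baselineGammaAmp = p$baselineGammaAmp, n1Amp = p$n1Amp,
               pinkNoiseSd = p$pinkNoiseSd,
               ipscIndepRate = p$ipscIndepRate,
               ipscSharedRate = p$ipscSharedRate, spikeRate = p$spikeRate,
               spikeSharedFrac = p$spikeSharedFrac,
               alternationLapse = p$alternationLapse,
               ppiAttenuation = paste(sprintf("%s:%g", names(p$ppiAttenuation),
                                              p$ppiAttenuation),
                                      collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
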