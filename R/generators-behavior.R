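# Behavioural session generators: Y-maze arm-entry sequences and acoustic
# startle tables for prepulse inhibition.

#' Generate a Y-maze session
#'
#' Simulates a sequence of arm entries over arms \{A, B, C\}.  Policies:
#' \describe{
#'   \item{\code{"alternating"}}{always enter the least recently visited
#'     arm (perfect spatial working memory).}
#'   \item{\code{"random"}}{choose uniformly between the two arms other
#'     than the current one (an entry is always a transition).  The
#'     expected alternation index of this policy is exactly 50\%, the
#'     chance level.}
#'   \item{\code{"lapse"}}{alternating with probability
#'     \code{1 - lapseProb}, otherwise a random choice.}
#' }
#'
#' @param policy one of "alternating", "random", "lapse".
#' @param nEntries number of arm entries (>= 3).
#' @param seed integer seed.
#' @param lapseProb lapse probability for \code{policy = "lapse"}.
#' @return a [YMazeSession-class].
#' @examples
#' alternationIndex(generateYmazeSession("alternating", 12))
#' @export
generateYmazeSession <- function(policy = c("alternating", "random", "lapse"),
                                 nEntries = 15, seed = NULL, lapseProb = 0) {
  policy <- match.arg(policy)
  if (nEntries < 3) stop("nEntries must be >= 3")
  eps <- switch(policy, alternating = 0, random = 1, lapse = lapseProb)
  if (eps < 0 || eps > 1) stop("lapseProb must lie in [0, 1]")
  arms <- c("A", "B", "C")
  withSeed(seed, {
    entries <- character(nEntries)
    entries[1] <- sample(arms, 1)
    entries[2] <- sample(setdiff(arms, entries[1]), 1)
    for (i in 3:nEntries) {
      candidates <- setdiff(arms, entries[i - 1])
      leastRecent <- setdiff(candidates, entries[i - 2]) # the arm not just left
      entries[i] <- if (stats::runif(1) < eps)
        sample(candidates, 1) else leastRecent
    }
    new("YMazeSession", entries = entries)
  })
}

#' Generate an acoustic startle session for PPI
#'
#' Pulse-alone startle amplitudes are log-normal around
#' \code{baselineStartle}; prepulse+pulse amplitudes are attenuated by the
#' preset's per-intensity \code{ppiAttenuation} before the same
#' multiplicative noise.  The pulse-alone startle amplitude itself does not
#' depend on the preset: condition contrasts act on the attenuation only.
#'
#' @param preset a [GenotypePreset-class] (supplies \code{ppiAttenuation}).
#' @param baselineStartle median pulse-alone startle amplitude (a.u., > 0).
#' @param nTrialsPerType trials per trial type.
#' @param noiseSdLog sd of the log-normal multiplicative noise.
#' @param seed integer seed.
#' @return a [StartleSession-class].
#' @examples
#' s <- generatePpiSession(makePreset("control"), seed = 1)
#' ppiPercent(s)
#' @export
generatePpiSession <- function(preset, baselineStartle = 100,
                               nTrialsPerType = 10, noiseSdLog = 0.2,
                               seed = NULL) {
  stopifnot(is(preset, "GenotypePreset"))
  if (baselineStartle <= 0) stop("baselineStartle must be > 0")
  att <- preset@ppiAttenuation
  withSeed(seed, {
    rows <- list(data.frame(
      trialType = "pulse_alone", intensity = NA_real_,
      amplitude = baselineStartle *
        stats::rlnorm(nTrialsPerType, 0, noiseSdLog)))
    for (k in seq_along(att)) {
      rows[[k + 1]] <- data.frame(
        trialType = "prepulse", intensity = as.numeric(names(att)[k]),
        amplitude = baselineStartle * (1 - att[k]) *
          stats::rlnorm(nTrialsPerType, 0, noiseSdLog))
    }
    new("StartleSession", trials = do.call(rbind, rows))
  })
}
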