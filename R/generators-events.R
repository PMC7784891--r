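# Poisson-mixture generators for paired sIPSC event trains and correlated
# spike-train pairs.

#' Generate a paired sIPSC event train
#'
#' Each cell receives an independent homogeneous Poisson stream of rate
#' \code{indepRate}, plus a shared Poisson stream of rate \code{sharedRate}
#' whose events are copied to both cells with independent uniform
#' (+/- \code{jitterHalfwidth}) jitter.  The total per-cell event rate is
#' therefore \code{indepRate + sharedRate}.  Amplitudes are log-normal with
#' ~20 pA median, truncated to exceed \code{ampMin} (the detection
#' threshold convention is a strict "> 5 pA").
#'
#' With the default +/-3 ms jitter, two copies of a shared event are at
#' most 6 ms apart and always fall inside the +/-10 ms coincidence window
#' of [synchronousFraction()].
#'
#' @param indepRate independent event rate per cell (Hz).
#' @param sharedRate rate of events shared by both cells (Hz).
#' @param duration recording duration (s).
#' @param jitterHalfwidth half-width (s) of the uniform jitter applied to
#'   each copy of a shared event (default 0.003).
#' @param seed integer seed.
#' @param ampMedian,ampSdLog log-normal amplitude parameters (pA).
#' @param ampMin lower truncation bound for amplitudes (pA).
#' @return an [IPSCEventTrains-class].
#' @examples
#' tr <- generateEventTrainPair(2.848, 0.645, duration = 60, seed = 1)
#' synchronousFraction(tr)
#' @export
generateEventTrainPair <- function(indepRate, sharedRate, duration,
                                   jitterHalfwidth = 0.003, seed = NULL,
                                   ampMedian = 20, ampSdLog = 0.35,
                                   ampMin = 5) {
  if (indepRate < 0 || sharedRate < 0) stop("rates must be >= 0")
  if (duration <= 0) stop("duration must be > 0")
  if (jitterHalfwidth < 0) stop("jitterHalfwidth must be >= 0")
  withSeed(seed, {
    shared <- rPoissonProcess(sharedRate, duration)
    jitA <- if (jitterHalfwidth > 0)
      stats::runif(length(shared), -jitterHalfwidth, jitterHalfwidth) else 0
    jitB <- if (jitterHalfwidth > 0)
      stats::runif(length(shared), -jitterHalfwidth, jitterHalfwidth) else 0
    a <- sort(c(rPoissonProcess(indepRate, duration), shared + jitA))
    b <- sort(c(rPoissonProcess(indepRate, duration), shared + jitB))
    new("IPSCEventTrains",
        timesA = a, timesB = b,
        ampsA = .rIpscAmps(length(a), ampMedian, ampSdLog, ampMin),
        ampsB = .rIpscAmps(length(b), ampMedian, ampSdLog, ampMin),
        duration = duration)
  })
}

# truncated log-normal amplitudes (resample below ampMin; rarely triggered)
.rIpscAmps <- function(n, median, sdLog, ampMin) {
  x <- stats::rlnorm(n, log(median), sdLog)
  while (any(bad <- x <= ampMin))
    x[bad] <- stats::rlnorm(sum(bad), log(median), sdLog)
  x
}

#' Render paired sIPSC current traces from event trains
#'
#' Convolves each event with a difference-of-exponentials synaptic kernel
#' (normalized to unit peak, so the trace peak of an isolated event equals
#' its amplitude) and adds Gaussian noise.  Traces are stored as positive
#' IPSC magnitudes (outward currents rectified at ingestion).
#'
#' The kernel peaks \code{riseTau * decayTau / (decayTau - riseTau) *
#' log(decayTau / riseTau)} seconds after the event time; [detectIpscEvents()]
#' reports peak times, so recovered times carry that fixed delay.
#'
#' @param trains an [IPSCEventTrains-class].
#' @param sampleRate sampling rate (Hz); must give at least 4 samples per
#'   rise time constant.
#' @param riseTau,decayTau kernel time constants (s); decayTau > riseTau > 0.
#' @param noiseSd Gaussian noise sd (pA).
#' @param seed integer seed for the noise.
#' @return list with \code{time}, \code{traceA}, \code{traceB},
#'   \code{sampleRate} and \code{peakDelay} (s).
#' @export
renderIpscTraces <- function(trains, sampleRate = 10000, riseTau = 5e-4,
                             decayTau = 5e-3, noiseSd = 0, seed = NULL) {
  stopifnot(is(trains, "IPSCEventTrains"))
  if (!(decayTau > riseTau && riseTau > 0))
    stop("need decayTau > riseTau > 0")
  if (sampleRate * riseTau < 4)
    stop("sampleRate too low to resolve the rise time: need >= 4 samples ",
         "per riseTau (", ceiling(4 / riseTau), " Hz)")
  n <- ceiling(trains@duration * sampleRate)
  kLen <- ceiling(8 * decayTau * sampleRate)
  tk <- (seq_len(kLen) - 1) / sampleRate
  kernel <- exp(-tk / decayTau) - exp(-tk / riseTau)
  kernel <- kernel / max(kernel)
  render <- function(times, amps) {
    x <- numeric(n + kLen)
    idx <- floor(times * sampleRate) + 1
    keep <- idx >= 1 & idx <= n
    for (j in which(keep)) {
      rng <- idx[j]:(idx[j] + kLen - 1)
      x[rng] <- x[rng] + amps[j] * kernel
    }
    x[seq_len(n)]
  }
  withSeed(seed, {
    a <- render(trains@timesA, trains@ampsA)
    b <- render(trains@timesB, trains@ampsB)
    if (noiseSd > 0) {
      a <- a + stats::rnorm(n, 0, noiseSd)
      b <- b + stats::rnorm(n, 0, noiseSd)
    }
    list(time = (seq_len(n) - 1) / sampleRate, traceA = a, traceB = b,
         sampleRate = sampleRate,
         peakDelay = riseTau * decayTau / (decayTau - riseTau) *
           log(decayTau / riseTau))
  })
}

#' Generate a correlated spike-train pair
#'
#' Both units fire as the superposition of a shared Poisson component of
#' rate \code{sharedFrac * rate} (events injected into both trains at the
#' same time) and independent Poisson components of rate
#' \code{(1 - sharedFrac) * rate} each.  The marginal rate of each train is
#' \code{rate}, and the expected zero-lag Pearson correlation of binned
#' counts (fine bins) equals \code{sharedFrac}.
#'
#' @param rate marginal firing rate per unit (Hz).
#' @param sharedFrac fraction of each unit's spikes drawn from the shared
#'   component, in [0, 1].
#' @param duration session duration (s).
#' @param seed integer seed.
#' @param unitIds length-2 unit identifiers.
#' @return a [SpikeTrainPair-class].
#' @examples
#' p <- generateSpikePair(6, 0.3, duration = 120, seed = 1)
#' crossCorrelation(p)
#' @export
generateSpikePair <- function(rate, sharedFrac, duration, seed = NULL,
                              unitIds = c("u1", "u2")) {
  if (sharedFrac < 0 || sharedFrac > 1) stop("sharedFrac must lie in [0, 1]")
  if (rate < 0) stop("rate must be >= 0")
  if (duration <= 0) stop("duration must be > 0")
  withSeed(seed, {
    shared <- rPoissonProcess(sharedFrac * rate, duration)
    a <- .dedupeSorted(sort(c(rPoissonProcess((1 - sharedFrac) * rate, duration), shared)))
    b <- .dedupeSorted(sort(c(rPoissonProcess((1 - sharedFrac) * rate, duration), shared)))
    new("SpikeTrainPair", timesA = a, timesB = b, duration = duration,
        unitIds = unitIds)
  })
}

# enforce strict sorting (coincident continuous times have probability 0,
# but floating ties would violate the class invariant)
.dedupeSorted <- function(t) {
  if (length(t) < 2) return(t)
  t[c(TRUE, diff(t) > 0)]
}
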