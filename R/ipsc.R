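# sIPSC event detection and synchronous-GABA-release quantification via
# the +/-10 ms coincidence rule.

#' Detect sIPSC events in a voltage-clamp current trace
#'
#' The trace is assumed to hold positive IPSC magnitudes (inward currents
#' rectified at ingestion).  A running-median baseline is subtracted, local
#' maxima of the residual exceeding the threshold are collected, and peaks
#' closer than \code{minSeparation} are pruned largest-first.  Events with
#' amplitude <= \code{threshold} are excluded -- the threshold is strict
#' ("> 5 pA"), so an exactly-5-pA peak is rejected.
#'
#' Reported times are peak times; an isolated rendered event peaks a fixed
#' kernel delay after its event time (see [renderIpscTraces()]).
#'
#' @param trace numeric vector of IPSC magnitudes (pA).
#' @param sampleRate sampling rate (Hz, >= 2000).
#' @param threshold amplitude threshold (pA), strict; default 5.
#' @param minSeparation minimum peak separation (s), default 0.002.
#' @param baselineHalfwidth half-width (s) of the running-median baseline
#'   window, default 0.025.
#' @return data.frame with columns \code{time} (s) and \code{amplitude}
#'   (pA), time-ordered; zero rows for a flat trace.
#' @export
detectIpscEvents <- function(trace, sampleRate, threshold = 5,
                             minSeparation = 0.002,
                             baselineHalfwidth = 0.025) {
  if (sampleRate < 2000) stop("sampleRate must be >= 2 kHz")
  n <- length(trace)
  empty <- data.frame(time = numeric(0), amplitude = numeric(0))
  if (n < 3) return(empty)
  k <- 2L * floor(baselineHalfwidth * sampleRate) + 1L
  k <- min(k, if (n %% 2 == 1) n else n - 1L)
  d <- trace - stats::runmed(trace, k)
  inner <- 2:(n - 1)
  isPeak <- d[inner] > d[inner - 1] & d[inner] >= d[inner + 1] &
    d[inner] > threshold
  idx <- inner[isPeak]
  if (!length(idx)) return(empty)
  # Greedily accept peaks largest-first.  A candidate must (a) be at least
  # minSeparation from every accepted peak and (b) rise more than the
  # threshold above the trough separating it from its nearest accepted
  # neighbour (prominence), which rejects noise wiggles riding the decay
  # shoulder of a larger event.
  ord <- idx[order(d[idx], decreasing = TRUE)]
  minGap <- minSeparation * sampleRate
  kept <- integer(0)
  for (i in ord) {
    if (length(kept)) {
      if (any(abs(kept - i) < minGap)) next
      nearest <- kept[which.min(abs(kept - i))]
      trough <- min(d[min(i, nearest):max(i, nearest)])
      if (d[i] - trough <= threshold) next
    }
    kept <- c(kept, i)
  }
  kept <- sort(kept)
  data.frame(time = (kept - 1) / sampleRate, amplitude = d[kept])
}

#' Synchronous sIPSC fraction of a cell pair
#'
#' An event is synchronous iff the other cell has at least one event
#' within \code{windowHalfwidth} (closed interval, default +/-10 ms).  The
#' headline percentage pools the events of both cells:
#' \code{100 * (sync_A + sync_B) / (n_A + n_B)}, which makes the result
#' symmetric in (A, B) and bounded by [0, 100]; the per-cell percentages
#' are also reported.  Computed by a sorted two-sided search in
#' O(n log n).
#'
#' @param trains an [IPSCEventTrains-class] (sorted).
#' @param windowHalfwidth coincidence half-width (s), default 0.010.
#' @return a [SynchronyResult-class].
#' @examples
#' tr <- generateEventTrainPair(2.848, 0.645, 60, seed = 1)
#' synchronousFraction(tr)
#' @export
synchronousFraction <- function(trains, windowHalfwidth = 0.010) {
  stopifnot(is(trains, "IPSCEventTrains"))
  if (windowHalfwidth <= 0) stop("windowHalfwidth must be > 0")
  a <- trains@timesA
  b <- trains@timesB
  if (length(a) == 0 || length(b) == 0) {
    warning("empty event train: synchronous percentage set to 0")
    return(new("SynchronyResult", pctSynchronous = 0,
               perCellPct = c(A = 0, B = 0),
               windowHalfwidth = windowHalfwidth,
               nEventsA = length(a), nEventsB = length(b),
               meanIeiA = .meanIei(a), meanIeiB = .meanIei(b)))
  }
  w <- windowHalfwidth
  nSyncIn <- function(x, other) {
    # other events in [x - w, x + w], closed on both sides
    hi <- findInterval(x + w, other)                     # other <= x + w
    lo <- findInterval(x - w, other, left.open = TRUE)   # other <  x - w
    sum(hi - lo >= 1)
  }
  sa <- nSyncIn(a, b)
  sb <- nSyncIn(b, a)
  new("SynchronyResult",
      pctSynchronous = 100 * (sa + sb) / (length(a) + length(b)),
      perCellPct = c(A = 100 * sa / length(a), B = 100 * sb / length(b)),
      windowHalfwidth = windowHalfwidth,
      nEventsA = length(a), nEventsB = length(b),
      meanIeiA = .meanIei(a), meanIeiB = .meanIei(b))
}

.meanIei <- function(t) if (length(t) >= 2) mean(diff(t)) else NA_real_

#' Closed-form synchronous fraction for a Poisson mixture
#'
#' For two cells with total per-cell event rate \code{r} of which
#' \code{s} is shared (jitter small relative to the window), the expected
#' synchronous fraction under the +/-\code{w} coincidence rule is
#' \deqn{[s + (r - s)(1 - e^{-2wr})] / r:}
#' a shared event always has its partner copy inside the window, and an
#' independent event finds at least one of the other cell's events in its
#' 2w window with probability \eqn{1 - e^{-2wr}}.
#'
#' @param totalRate total per-cell event rate r (Hz).
#' @param sharedRate shared event rate s (Hz).
#' @param windowHalfwidth coincidence half-width w (s), default 0.010.
#' @return expected synchronous percentage (0--100).
#' @export
expectedSynchronousPct <- function(totalRate, sharedRate,
                                   windowHalfwidth = 0.010) {
  stopifnot(totalRate >= sharedRate, sharedRate >= 0)
  if (totalRate == 0) return(0)
  r <- totalRate
  s <- sharedRate
  100 * (s + (r - s) * (1 - exp(-2 * windowHalfwidth * r))) / r
}

#' Inter-event interval summary
#'
#' Successive-difference intervals of an event train; for an
#' [IPSCEventTrains-class] both cells are summarized.
#'
#' @param x sorted numeric event times (s), or an [IPSCEventTrains-class].
#' @param ... unused.
#' @return for numeric input, a list with \code{mean}, \code{sd}, \code{n}
#'   and the \code{intervals}; for paired trains, a list with per-cell
#'   summaries \code{a}, \code{b} and the pooled \code{grandMean}.
#' @rdname interEventIntervals
#' @export
setMethod("interEventIntervals", "numeric", function(x, ...) {
  if (length(x) < 2) stop("need at least 2 events for intervals")
  if (is.unsorted(x)) stop("event times must be sorted")
  iv <- diff(x)
  list(mean = mean(iv), sd = stats::sd(iv), n = length(iv), intervals = iv)
})

#' @rdname interEventIntervals
#' @export
setMethod("interEventIntervals", "IPSCEventTrains", function(x, ...) {
  a <- interEventIntervals(x@timesA)
  b <- interEventIntervals(x@timesB)
  list(a = a, b = b,
       grandMean = mean(c(a$intervals, b$intervals)))
})
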