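# In vivo spike synchrony: binned cross-correlation of simultaneously
# recorded pyramidal-cell pairs, with an ISI-shuffle null.

#' Bin a spike-train pair into count vectors
#'
#' Counts spikes in half-open bins \code{[k*binWidth, (k+1)*binWidth)} over
#' \code{[0, duration)}.  The number of bins is
#' \code{floor(duration / binWidth)}; spikes at or beyond the last full bin
#' (i.e. at t = duration when duration is a bin multiple) are dropped.
#'
#' @param pair a [SpikeTrainPair-class].
#' @param binWidth bin width in seconds (default 0.005).
#' @return list with integer vectors \code{countsA}, \code{countsB},
#'   \code{binWidth} and \code{nBins}.
#' @export
binSpikeTrains <- function(pair, binWidth = 0.005) {
  stopifnot(is(pair, "SpikeTrainPair"))
  if (binWidth <= 0) stop("binWidth must be > 0")
  if (pair@duration < 100 * binWidth)
    stop("duration must be at least 100 bin widths")
  nBins <- as.integer(floor(pair@duration / binWidth))
  binOne <- function(t) {
    idx <- floor(t / binWidth) + 1
    idx <- idx[idx >= 1 & idx <= nBins]
    tabulate(idx, nbins = nBins)
  }
  list(countsA = binOne(pair@timesA), countsB = binOne(pair@timesB),
       binWidth = binWidth, nBins = nBins)
}

#' Spike-pair cross-correlation
#'
#' The synchrony coefficient is the zero-lag Pearson correlation of the
#' binned spike counts; the correlogram gives the same correlation at
#' integer-bin lags out to \code{maxLag}.  A count vector with zero
#' variance (empty or metronomic train) yields a flagged missing
#' coefficient, not 0.
#'
#' @param pair a [SpikeTrainPair-class] with both trains non-empty.
#' @param binWidth bin width (s), default 0.005.
#' @param maxLag correlogram extent (s), default 0.1.
#' @return a [CrossCorrResult-class].
#' @export
crossCorrelation <- function(pair, binWidth = 0.005, maxLag = 0.1) {
  stopifnot(is(pair, "SpikeTrainPair"))
  if (length(pair@timesA) == 0 || length(pair@timesB) == 0)
    stop("both trains must be non-empty")
  b <- binSpikeTrains(pair, binWidth)
  r <- .safeCor(b$countsA, b$countsB)
  lags <- -round(maxLag / binWidth):round(maxLag / binWidth)
  n <- b$nBins
  rl <- vapply(lags, function(k) {
    if (k >= 0) .safeCor(b$countsA[1:(n - k)], b$countsB[(1 + k):n])
    else .safeCor(b$countsA[(1 - k):n], b$countsB[1:(n + k)])
  }, numeric(1))
  new("CrossCorrResult", coefficient = r,
      correlogram = data.frame(lag = lags * binWidth, r = rl),
      binWidth = binWidth, nBins = as.numeric(n),
      nullMean = NA_real_, nullSd = NA_real_, nullQuantile = NA_real_)
}

# permute inter-spike intervals, keeping the first spike time: preserves
# the spike count and the ISI multiset exactly
.isiShuffle <- function(times) times[1] + c(0, cumsum(sample(diff(times))))

.safeCor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero-variance count vector: correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Shuffle null for the spike-pair correlation
#'
#' Builds a rate- and ISI-distribution-preserving null by permuting the
#' inter-spike intervals of train B (the spike count and the ISI multiset
#' are preserved exactly) and recomputing the zero-lag correlation for
#' each shuffle.
#'
#' @param pair a [SpikeTrainPair-class]; both trains need >= 3 spikes.
#' @param nShuffles number of shuffles (>= 20).
#' @param binWidth bin width (s) passed to [crossCorrelation()].
#' @param seed integer seed for the permutations.
#' @return a [CrossCorrResult-class] whose \code{nullMean}, \code{nullSd}
#'   and \code{nullQuantile} slots are filled; the raw null draws are in
#'   \code{attr(, "null")}.
#' @export
shuffleNull <- function(pair, nShuffles = 100, binWidth = 0.005,
                        seed = NULL) {
  stopifnot(is(pair, "SpikeTrainPair"))
  if (nShuffles < 20) stop("need at least 20 shuffles")
  if (length(pair@timesA) < 3 || length(pair@timesB) < 3)
    stop("both trains need at least 3 spikes for an ISI shuffle")
  obs <- crossCorrelation(pair, binWidth)
  null <- withSeed(seed, vapply(seq_len(nShuffles), function(i) {
    shuf <- new("SpikeTrainPair", timesA = pair@timesA,
                timesB = .dedupeSorted(.isiShuffle(pair@timesB)),
                duration = pair@duration, unitIds = pair@unitIds)
    crossCorrelation(shuf, binWidth)@coefficient
  }, numeric(1)))
  obs@nullMean <- mean(null)
  obs@nullSd <- stats::sd(null)
  obs@nullQuantile <- mean(null < obs@coefficient)
  attr(obs, "null") <- null
  obs
}
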