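# Scalar quantifiers: corrected total cell fluorescence and behaviour
# scores (Y-maze spontaneous alternation, percent prepulse inhibition).

#' Corrected total cell fluorescence (CTCF)
#'
#' \code{CTCF = integratedDensity - area * backgroundMean}, the standard
#' ImageJ ROI correction.  Negative values are possible (cell dimmer than
#' background) and are returned as-is with a warning.
#'
#' @param integratedDensity ROI integrated density (a.u.).
#' @param area ROI area (px^2 or um^2), > 0.
#' @param backgroundMean mean background fluorescence per unit area, >= 0.
#' @return CTCF in a.u. (vectorized).
#' @examples
#' ctcf(1000, 50, 4)   # 800
#' @export
ctcf <- function(integratedDensity, area, backgroundMean) {
  stopifnot(all(is.finite(integratedDensity)), all(is.finite(area)),
            all(is.finite(backgroundMean)))
  if (any(area <= 0)) stop("area must be > 0")
  if (any(backgroundMean < 0)) stop("backgroundMean must be >= 0")
  out <- integratedDensity - area * backgroundMean
  if (any(out < 0)) warning(sum(out < 0), " cell(s) with negative CTCF")
  out
}

#' Normalized fluorescence relative to a reference group
#'
#' Each cell's CTCF is expressed as a percentage of the mean CTCF of a
#' reference group (e.g. non-PV neurons of control animals), so the
#' reference-group mean maps to 100\% by construction.
#'
#' @param cells data.frame with either a \code{ctcf} column or the three
#'   columns \code{integratedDensity}, \code{area}, \code{backgroundMean}.
#' @param reference logical vector (length nrow(cells)) selecting the
#'   reference cells; must select a non-empty group with positive mean
#'   CTCF.
#' @return the input data.frame with columns \code{ctcf} and
#'   \code{normalizedPct} added.
#' @export
normalizedFluorescence <- function(cells, reference) {
  stopifnot(is.data.frame(cells), is.logical(reference),
            length(reference) == nrow(cells))
  if (!"ctcf" %in% names(cells)) {
    need <- c("integratedDensity", "area", "backgroundMean")
    if (!all(need %in% names(cells)))
      stop("cells needs a 'ctcf' column or columns: ",
           paste(need, collapse = ", "))
    cells$ctcf <- ctcf(cells$integratedDensity, cells$area,
                       cells$backgroundMean)
  }
  if (!any(reference)) stop("reference group is empty")
  refMean <- mean(cells$ctcf[reference])
  if (refMean <= 0) stop("reference group mean CTCF must be > 0")
  cells$normalizedPct <- 100 * cells$ctcf / refMean
  cells
}

#' Y-maze spontaneous alternation index
#'
#' Percentage of overlapping triplets of consecutive arm entries that
#' visit three distinct arms:
#' \code{100 * #\{distinct triplets\} / (n - 2)}.  With three arms and
#' transitions only (consecutive entries differ), a memoryless random
#' explorer scores 50\% in expectation -- the chance level.
#'
#' @param x a [YMazeSession-class] or a character vector of arm entries
#'   over \{A, B, C\} with consecutive entries differing.
#' @return alternation index in percent.
#' @examples
#' alternationIndex(c("A", "B", "C", "A", "B", "C"))  # 100
#' alternationIndex(c("A", "B", "A", "B", "A"))       # 0
#' @rdname alternationIndex
#' @export
setMethod("alternationIndex", "character", function(x) {
  n <- length(x)
  if (n < 3) stop("need at least 3 arm entries")
  if (any(x[-1] == x[-n]))
    stop("invalid transition log: consecutive entries must differ")
  if (!all(x %in% c("A", "B", "C"))) stop("entries must be in {A, B, C}")
  triplets <- vapply(seq_len(n - 2),
                     function(i) length(unique(x[i:(i + 2)])) == 3L,
                     logical(1))
  100 * sum(triplets) / (n - 2)
})

#' @rdname alternationIndex
#' @export
setMethod("alternationIndex", "YMazeSession",
          function(x) alternationIndex(x@entries))

#' Percent prepulse inhibition
#'
#' \code{\%PPI(i) = 100 * (mean pulse-alone - mean prepulse(i)+pulse) /
#' mean pulse-alone}, per prepulse intensity, using per-intensity trial
#' means.  Facilitation (prepulse+pulse exceeding pulse-alone) yields a
#' negative percentage, returned unclipped.
#'
#' @param x a [StartleSession-class] or a data.frame with columns
#'   \code{trialType}, \code{intensity}, \code{amplitude}.
#' @return data.frame with one row per prepulse intensity
#'   (\code{intensity}, \code{ppi}) plus the pulse-alone mean as attribute
#'   \code{"pulseAloneMean"}.
#' @rdname ppiPercent
#' @export
setMethod("ppiPercent", "data.frame", function(x) {
  stopifnot(all(c("trialType", "intensity", "amplitude") %in% names(x)))
  pulse <- x$amplitude[x$trialType == "pulse_alone"]
  if (!length(pulse)) stop("need at least one pulse-alone trial")
  pulseMean <- mean(pulse)
  if (pulseMean == 0) stop("mean pulse-alone startle is zero")
  pp <- x[x$trialType == "prepulse", , drop = FALSE]
  if (!nrow(pp)) stop("need at least one prepulse trial")
  means <- stats::aggregate(amplitude ~ intensity, data = pp, FUN = mean)
  out <- data.frame(intensity = means$intensity,
                    ppi = 100 * (pulseMean - means$amplitude) / pulseMean)
  attr(out, "pulseAloneMean") <- pulseMean
  out
})

#' @rdname ppiPercent
#' @export
setMethod("ppiPercent", "StartleSession", function(x) ppiPercent(x@trials))
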