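# Plain-text interchange: CSV readers/writers for the documented schemas.

#' Read spike-train pairs from CSV
#'
#' Expects columns \code{unit_id} and \code{time_s}; every pair of units is
#' returned as a [SpikeTrainPair-class].
#'
#' @param path CSV file path.
#' @param duration session duration (s); defaults to the latest spike time.
#' @return named list of [SpikeTrainPair-class] objects ("u1:u2").
#' @export
readSpikeTimes <- function(path, duration = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("unit_id", "time_s") %in% names(d)))
  if (is.null(duration)) duration <- max(d$time_s)
  units <- sort(unique(d$unit_id))
  if (length(units) < 2) stop("need at least two units")
  pairs <- utils::combn(units, 2, simplify = FALSE)
  out <- lapply(pairs, function(p) {
    new("SpikeTrainPair",
        timesA = .dedupeSorted(sort(d$time_s[d$unit_id == p[1]])),
        timesB = .dedupeSorted(sort(d$time_s[d$unit_id == p[2]])),
        duration = duration, unitIds = as.character(p))
  })
  names(out) <- vapply(pairs, paste, "", collapse = ":")
  out
}

#' Read paired voltage-clamp traces from CSV
#'
#' Expects columns \code{time_s}, \code{i_a_pA}, \code{i_b_pA} on a uniform
#' time grid; currents are rectified to positive IPSC magnitudes.
#'
#' @param path CSV file path.
#' @return list with \code{traceA}, \code{traceB}, \code{sampleRate}.
#' @export
readPairedTraces <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_s", "i_a_pA", "i_b_pA") %in% names(d)))
  dt <- diff(d$time_s)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt))
    stop("time_s must be a uniform, increasing grid")
  list(traceA = abs(d$i_a_pA), traceB = abs(d$i_b_pA),
       sampleRate = 1 / mean(dt))
}

#' Read / write long-format metric tables
#'
#' @param metrics a metric table (subject, channel, condition, metric,
#'   value).
#' @param path CSV file path.
#' @return \code{readMetricTable} returns the data.frame;
#'   \code{writeMetricTable} returns the path invisibly.
#' @export
writeMetricTable <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMetricTable
#' @export
readMetricTable <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "channel", "condition", "metric", "value")
  if (!all(need %in% names(d)))
    stop("metric table must have columns: ", paste(need, collapse = ", "))
  d
}
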