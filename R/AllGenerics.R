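# Generics for accessors and the operations dispatched on data classes.

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("trials", function(x) standardGeneric("trials"))
#' @rdname accessors
#' @export
setGeneric("midIsiSegments", function(x) standardGeneric("midIsiSegments"))
#' @rdname accessors
#' @export
setGeneric("prestimRecord", function(x) standardGeneric("prestimRecord"))
#' @rdname accessors
#' @export
setGeneric("trialWindow", function(x) standardGeneric("trialWindow"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("channelId", function(x) standardGeneric("channelId"))
#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
#' @rdname accessors
#' @export
setGeneric("presetLabel", function(x) standardGeneric("presetLabel"))
#' @rdname accessors
#' @export
setGeneric("timesA", function(x) standardGeneric("timesA"))
#' @rdname accessors
#' @export
setGeneric("timesB", function(x) standardGeneric("timesB"))
#' @rdname accessors
#' @export
setGeneric("amplitudesA", function(x) standardGeneric("amplitudesA"))
#' @rdname accessors
#' @export
setGeneric("amplitudesB", function(x) standardGeneric("amplitudesB"))
#' @rdname accessors
#' @export
setGeneric("recordingDuration", function(x) standardGeneric("recordingDuration"))
#' @rdname accessors
#' @export
setGeneric("armEntries", function(x) standardGeneric("armEntries"))
#' @rdname accessors
#' @export
setGeneric("startleTrials", function(x) standardGeneric("startleTrials"))
#' @rdname accessors
#' @export
setGeneric("specPower", function(x) standardGeneric("specPower"))

#' @rdname zscoreLfp
#' @export
setGeneric("zscoreLfp", function(x) standardGeneric("zscoreLfp"))
#' @rdname assrPower
#' @export
setGeneric("assrPower",
  function(x, mode = c("evoked", "total"), band = c(35, 44),
           window = c(0.3, 0.5), spontaneous = c("power", "trace"), ...)
    standardGeneric("assrPower"))
#' @rdname baselinePower
#' @export
setGeneric("baselinePower",
  function(x, band = c(35, 44), ...) standardGeneric("baselinePower"))
#' @rdname intertrialCoherence
#' @export
setGeneric("intertrialCoherence",
  function(x, band = c(35, 44), window = c(0.3, 0.5), ...)
    standardGeneric("intertrialCoherence"))
#' @rdname n1Amplitude
#' @export
setGeneric("n1Amplitude",
  function(x, searchWindow = c(0.01, 0.1)) standardGeneric("n1Amplitude"))
#' @rdname interEventIntervals
#' @export
setGeneric("interEventIntervals",
  function(x, ...) standardGeneric("interEventIntervals"))
#' @rdname alternationIndex
#' @export
setGeneric("alternationIndex", function(x) standardGeneric("alternationIndex"))
#' @rdname ppiPercent
#' @export
setGeneric("ppiPercent", function(x) standardGeneric("ppiPercent"))
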