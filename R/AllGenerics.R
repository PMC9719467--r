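#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @export
setGeneric("channelRole", function(x) standardGeneric("channelRole"))

#' @export
setGeneric("channels", function(x) standardGeneric("channels"))

#' @export
setGeneric("startTime", function(x) standardGeneric("startTime"))

#' @export
setGeneric("recordingDuration", function(x) standardGeneric("recordingDuration"))

#' @export
setGeneric("epochs", function(x) standardGeneric("epochs"))

#' @export
setGeneric("epochLength", function(x) standardGeneric("epochLength"))

#' @export
setGeneric("eventKind", function(x) standardGeneric("eventKind"))

#' @export
setGeneric("intervals", function(x) standardGeneric("intervals"))

#' @export
setGeneric("rswaEvents", function(x, ...) standardGeneric("rswaEvents"))

#' @export
setGeneric("scoreTable", function(x, ...) standardGeneric("scoreTable"))

#' @export
setGeneric("channelSummary", function(x) standardGeneric("channelSummary"))

#' @export
setGeneric("combinedSummary", function(x) standardGeneric("combinedSummary"))

#' @export
setGeneric("baselineTable", function(x, ...) standardGeneric("baselineTable"))

#' @export
setGeneric("discardedChannels", function(x) standardGeneric("discardedChannels"))

#' @export
setGeneric("remSegments", function(x, ...) standardGeneric("remSegments"))
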