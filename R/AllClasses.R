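# Central S4 containers: one EMG trace, a recording, a hypnogram, an event
# list, and the scored result object returned by scoreRecording().

#' @include AllGenerics.R
NULL

#' Recognised EMG channel roles
#'
#' The SINBAR montage records the mentalis (chin), flexor digitorum
#' superficialis (FDS, both forearms) and tibialis anterior (TA, both legs).
#' Channels mapped to \code{"other"} are carried but never scored.
#'
#' @export
EMG_ROLES <- c("mentalis", "fds_left", "fds_right", "ta_left", "ta_right",
               "other")

#' Sleep stage vocabulary used internally
#' @export
SLEEP_STAGES <- c("W", "N1", "N2", "N3", "REM", "UNSCORED")

EVENT_KINDS <- c("arousal", "respiratory", "snore")

#' EmgChannel: a single surface-EMG trace
#'
#' Amplitudes are stored in millivolt (mV), the unit all thresholds of the
#' scorer are expressed in (e.g. the 0.05 mV electrode-detachment criterion).
#'
#' @slot role character, one of \code{EMG_ROLES}.
#' @slot samples numeric vector of amplitudes in mV.
#' @slot fs sampling rate in Hz.
#' @export
setClass("EmgChannel",
         slots = c(role = "character", samples = "numeric", fs = "numeric"))

setValidity("EmgChannel", function(object) {
  msg <- character()
  if (length(object@role) != 1L || !object@role %in% EMG_ROLES)
    msg <- c(msg, sprintf("role must be one of: %s",
                          paste(EMG_ROLES, collapse = ", ")))
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (anyNA(object@samples) || any(!is.finite(object@samples)))
    msg <- c(msg, "samples must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct an EmgChannel
#'
#' @param role channel role, one of \code{EMG_ROLES}.
#' @param samples numeric amplitude vector in mV.
#' @param fs sampling rate in Hz.
#' @return An \linkS4class{EmgChannel}.
#' @export
EmgChannel <- function(role, samples, fs) {
  new("EmgChannel", role = as.character(role),
      samples = as.numeric(samples), fs = as.numeric(fs))
}

#' @describeIn EmgChannel amplitude samples (mV)
#' @param x an EmgChannel
#' @export
setMethod("samples", "EmgChannel", function(x) x@samples)

#' @describeIn EmgChannel sampling rate (Hz)
#' @export
setMethod("samplingRate", "EmgChannel", function(x) x@fs)

#' @describeIn EmgChannel channel role label
#' @export
setMethod("channelRole", "EmgChannel", function(x) x@role)

setMethod("show", "EmgChannel", function(object) {
  cat(sprintf("EmgChannel '%s': %d samples @ %g Hz (%.1f s), RMS %.4f mV\n",
              object@role, length(object@samples), object@fs,
              length(object@samples) / object@fs,
              sqrt(mean(object@samples^2))))
})

#' RecordingSet: the EMG channels of one polysomnography recording
#'
#' @slot channels list of \linkS4class{EmgChannel}, unique roles.
#' @slot startTime POSIXct start of the recording (from the EDF header).
#' @slot duration recording duration in seconds.
#' @export
setClass("RecordingSet",
         slots = c(channels = "list", startTime = "POSIXct",
                   duration = "numeric"))

setValidity("RecordingSet", function(object) {
  msg <- character()
  if (!all(vapply(object@channels, is, logical(1), "EmgChannel")))
    msg <- c(msg, "channels must all be EmgChannel objects")
  roles <- vapply(object@channels, channelRole, character(1))
  if (anyDuplicated(roles))
    msg <- c(msg, "channel roles must be unique within a recording")
  if (length(object@duration) != 1L || !is.finite(object@duration) ||
      object@duration <= 0)
    msg <- c(msg, "duration must be a single positive number")
  for (ch in object@channels) {
    if (abs(length(samples(ch)) - object@duration * samplingRate(ch)) > 0.5)
      msg <- c(msg, sprintf("channel '%s' length inconsistent with duration",
                            channelRole(ch)))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a RecordingSet
#'
#' @param channels list of \linkS4class{EmgChannel}.
#' @param startTime POSIXct recording start.
#' @param duration recording duration in seconds.
#' @return A \linkS4class{RecordingSet}.
#' @export
RecordingSet <- function(channels, startTime, duration) {
  names(channels) <- vapply(channels, channelRole, character(1))
  new("RecordingSet", channels = channels,
      startTime = as.POSIXct(startTime), duration = as.numeric(duration))
}

#' @describeIn RecordingSet named list of channels
#' @param x a RecordingSet
#' @export
setMethod("channels", "RecordingSet", function(x) x@channels)

#' @describeIn RecordingSet recording start (POSIXct)
#' @export
setMethod("startTime", "RecordingSet", function(x) x@startTime)

#' @describeIn RecordingSet duration in seconds
#' @export
setMethod("recordingDuration", "RecordingSet", function(x) x@duration)

#' @export
setMethod("[[", "RecordingSet", function(x, i) x@channels[[i]])

setMethod("show", "RecordingSet", function(object) {
  cat(sprintf("RecordingSet: %d channel(s), %.1f s, start %s\n",
              length(object@channels), object@duration,
              format(object@startTime, "%Y-%m-%d %H:%M:%S")))
  for (ch in object@channels) show(ch)
})

#' Hypnogram: 30-s sleep-stage epochs anchored to recording time
#'
#' @slot epochs data.frame with columns \code{start} (recording-relative
#'   seconds) and \code{stage} (factor with levels \code{SLEEP_STAGES}).
#' @slot epochLength epoch length in seconds, fixed at 30.
#' @export
setClass("Hypnogram",
         slots = c(epochs = "data.frame", epochLength = "numeric"))

setValidity("Hypnogram", function(object) {
  msg <- character()
  e <- object@epochs
  if (!all(c("start", "stage") %in% names(e)))
    msg <- c(msg, "epochs must have columns 'start' and 'stage'")
  else {
    if (!all(levels(e$stage) == SLEEP_STAGES))
      msg <- c(msg, "stage must be a factor with levels SLEEP_STAGES")
    if (nrow(e) > 1 && any(diff(e$start) < object@epochLength - 1e-9))
      msg <- c(msg, "epochs must be non-overlapping and sorted")
  }
  if (length(object@epochLength) != 1L || object@epochLength <= 0)
    msg <- c(msg, "epochLength must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a Hypnogram
#'
#' @param start numeric vector of epoch starts, recording-relative seconds.
#' @param stage character or factor of stages (levels \code{SLEEP_STAGES}).
#' @param epochLength epoch length in seconds (30 by standard PSG scoring).
#' @return A \linkS4class{Hypnogram}.
#' @export
Hypnogram <- function(start, stage, epochLength = 30) {
  stage <- factor(as.character(stage), levels = SLEEP_STAGES)
  if (anyNA(stage)) stop("unknown sleep stage; use one of: ",
                         paste(SLEEP_STAGES, collapse = ", "))
  new("Hypnogram",
      epochs = data.frame(start = as.numeric(start), stage = stage),
      epochLength = epochLength)
}

#' @describeIn Hypnogram epoch table (start, stage)
#' @param x a Hypnogram
#' @export
setMethod("epochs", "Hypnogram", function(x) x@epochs)

#' @describeIn Hypnogram epoch length in seconds
#' @export
setMethod("epochLength", "Hypnogram", function(x) x@epochLength)

setMethod("show", "Hypnogram", function(object) {
  tab <- table(object@epochs$stage)
  cat(sprintf("Hypnogram: %d epochs of %g s (%s)\n",
              nrow(object@epochs), object@epochLength,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
})

#' EventList: scored PSG events of one kind
#'
#' @slot kind one of \code{"arousal"}, \code{"respiratory"}, \code{"snore"}.
#' @slot intervals data.frame with \code{start}, \code{end} in
#'   recording-relative seconds, sorted by start.
#' @export
setClass("EventList",
         slots = c(kind = "character", intervals = "data.frame"))

setValidity("EventList", function(object) {
  msg <- character()
  if (!object@kind %in% EVENT_KINDS)
    msg <- c(msg, sprintf("kind must be one of: %s",
                          paste(EVENT_KINDS, collapse = ", ")))
  iv <- object@intervals
  if (!all(c("start", "end") %in% names(iv)))
    msg <- c(msg, "intervals must have columns 'start' and 'end'")
  else if (nrow(iv)) {
    if (any(iv$end <= iv$start))
      msg <- c(msg, "all intervals must satisfy end > start")
    if (is.unsorted(iv$start))
      msg <- c(msg, "intervals must be sorted by start")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EventList
#'
#' @param kind event kind (\code{"arousal"}, \code{"respiratory"},
#'   \code{"snore"}).
#' @param start,end numeric vectors, recording-relative seconds.
#' @return An \linkS4class{EventList}.
#' @export
EventList <- function(kind, start = numeric(), end = numeric()) {
  o <- order(start)
  new("EventList", kind = kind,
      intervals = data.frame(start = as.numeric(start)[o],
                             end = as.numeric(end)[o]))
}

#' @describeIn EventList event kind
#' @param x an EventList
#' @export
setMethod("eventKind", "EventList", function(x) x@kind)

#' @describeIn EventList interval table (start, end)
#' @export
setMethod("intervals", "EventList", function(x) x@intervals)

setMethod("show", "EventList", function(object) {
  cat(sprintf("EventList '%s': %d interval(s), total %.1f s\n",
              object@kind, nrow(object@intervals),
              sum(object@intervals$end - object@intervals$start)))
})

#' RswaScoring: the complete result of scoring one recording
#'
#' Returned by \code{\link{scoreRecording}}. Per-channel results (activity
#' events, epoch/mini-epoch score tables, baseline assignments, artefact
#' masks) live in \code{channels}; access them through \code{rswaEvents},
#' \code{scoreTable}, \code{baselineTable}, \code{channelSummary},
#' \code{combinedSummary} and \code{discardedChannels}.
#'
#' @slot params the \code{\link{detectionParams}} list used.
#' @slot segments REM segment table (start, end, isPeriod).
#' @slot channels named list of per-channel result lists.
#' @slot summaries per-channel summary data.frame.
#' @slot combined combined-channel summary data.frame.
#' @slot discarded data.frame of discarded channels and reasons.
#' @slot policy artefact policy used ("full" or "arousal-only").
#' @export
setClass("RswaScoring",
         slots = c(params = "list", segments = "data.frame",
                   channels = "list", summaries = "data.frame",
                   combined = "data.frame", discarded = "data.frame",
                   policy = "character"))

#' @describeIn RswaScoring activity-event table; \code{role = NULL} binds all
#'   channels
#' @param x an RswaScoring
#' @param role optional channel role to restrict to
#' @param ... unused
#' @export
setMethod("rswaEvents", "RswaScoring", function(x, role = NULL, ...) {
  evs <- lapply(x@channels, `[[`, "events")
  ev <- do.call(rbind, evs)
  if (is.null(ev)) ev <- emptyEventTable()
  rownames(ev) <- NULL
  if (!is.null(role)) ev <- ev[ev$channel %in% role, , drop = FALSE]
  ev
})

#' @describeIn RswaScoring epoch and mini-epoch flags for one channel
#' @export
setMethod("scoreTable", "RswaScoring", function(x, role, ...) {
  ch <- x@channels[[role]]
  if (is.null(ch)) stop("channel not scored: ", role)
  list(epochs = ch$epochs, miniEpochs = ch$miniEpochs)
})

#' @describeIn RswaScoring per-channel summary table
#' @export
setMethod("channelSummary", "RswaScoring", function(x) x@summaries)

#' @describeIn RswaScoring combined-channel summary table
#' @export
setMethod("combinedSummary", "RswaScoring", function(x) x@combined)

#' @describeIn RswaScoring baseline assignment audit table
#' @export
setMethod("baselineTable", "RswaScoring", function(x, role = NULL, ...) {
  bt <- do.call(rbind, lapply(names(x@channels), function(r) {
    b <- x@channels[[r]]$baselines
    if (nrow(b)) cbind(channel = r, b) else NULL
  }))
  if (is.null(bt))
    bt <- data.frame(channel = character(), start = numeric(),
                     end = numeric(), isPeriod = logical(),
                     baseline = numeric(), source = character())
  if (!is.null(role)) bt <- bt[bt$channel %in% role, , drop = FALSE]
  rownames(bt) <- NULL
  bt
})

#' @describeIn RswaScoring channels dropped from scoring, with reasons
#' @export
setMethod("discardedChannels", "RswaScoring", function(x) x@discarded)

#' @describeIn RswaScoring REM segment table (start, end, isPeriod)
#' @export
setMethod("remSegments", "RswaScoring", function(x, ...) x@segments)

setMethod("show", "RswaScoring", function(object) {
  cat(sprintf("RswaScoring: %d channel(s) scored, %d REM segment(s), policy '%s'\n",
              length(object@channels), nrow(object@segments), object@policy))
  if (nrow(object@discarded))
    cat(sprintf("  discarded: %s\n",
                paste(sprintf("%s (%s)", object@discarded$channel,
                              object@discarded$reason), collapse = "; ")))
  if (nrow(object@summaries)) {
    s <- object@summaries
    for (i in seq_len(nrow(s)))
      cat(sprintf("  %-10s tonic %5.1f%%  phasic %5.1f%%  any %5.1f%%\n",
                  s$channel[i], s$pctTonic[i], s$pctPhasic[i], s$pctAny[i]))
  }
})

emptyEventTable <- function() {
  data.frame(channel = character(), category = character(),
             start = numeric(), end = numeric(), duration = numeric(),
             maxAmplitude = numeric())
}
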