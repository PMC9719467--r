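# Epoch / mini-epoch scoring and the end-to-end per-recording pipeline.

#' Score 3-s mini-epochs for phasic and any activity
#'
#' A valid mini-epoch is phasic when it overlaps at least one event of
#' duration up to 5 s, and carries any activity when it overlaps an event
#' of duration up to 15 s or lies inside a tonic 30-s epoch. Events longer
#' than 15 s outside tonic epochs contribute to neither flag. Inside tonic
#' epochs the rescored (elevated-baseline) events are used.
#'
#' @param events channel event data.frame (\code{start}, \code{end},
#'   \code{duration}) from ordinary scoring.
#' @param epochTable data.frame with \code{start}, \code{valid},
#'   \code{tonic} for each REM epoch.
#' @param params a \code{\link{detectionParams}} list.
#' @param tonicEvents named list (key: epoch start as character) of rescored
#'   event data.frames for tonic epochs.
#' @param miniValid optional logical vector of mini-epoch validity (10 per
#'   epoch, row-major); default all valid.
#' @return data.frame with \code{start}, \code{epochStart}, \code{valid},
#'   \code{phasic}, \code{any} per mini-epoch.
#' @export
scoreMiniEpochs <- function(events, epochTable, params = detectionParams(),
                            tonicEvents = list(), miniValid = NULL) {
  nm <- as.integer(round(params$epochLen / params$miniEpochLen))
  nMini <- nrow(epochTable) * nm
  starts <- rep(epochTable$start, each = nm) +
    rep((seq_len(nm) - 1L) * params$miniEpochLen, nrow(epochTable))
  if (is.null(miniValid)) miniValid <- rep(TRUE, nMini)
  epochStart <- rep(epochTable$start, each = nm)
  tonicHere <- rep(epochTable$tonic & epochTable$valid, each = nm)
  phasic <- logical(nMini)
  anyAct <- logical(nMini)

  overlapsAny <- function(ev, m0, m1, maxDur) {
    if (is.null(ev) || !nrow(ev)) return(FALSE)
    any(ev$duration <= maxDur + 1e-9 & ev$start < m1 - 1e-12 &
          ev$end > m0 + 1e-12)
  }
  for (i in seq_len(nMini)) {
    if (!miniValid[i]) next
    m0 <- starts[i]; m1 <- starts[i] + params$miniEpochLen
    if (tonicHere[i]) {
      ev <- tonicEvents[[as.character(epochStart[i])]]
      phasic[i] <- overlapsAny(ev, m0, m1, params$phasicMax)
      anyAct[i] <- TRUE
    } else {
      phasic[i] <- overlapsAny(events, m0, m1, params$phasicMax)
      anyAct[i] <- overlapsAny(events, m0, m1, params$intermediateMax)
    }
  }
  data.frame(start = starts, epochStart = epochStart, valid = miniValid,
             phasic = phasic, any = anyAct)
}

remEpochStarts <- function(segments, epochLen) {
  unlist(lapply(seq_len(nrow(segments)), function(i)
    seq(segments$start[i], segments$end[i] - epochLen, by = epochLen)))
}

allCellsValid <- function(mask, start, len) {
  a <- as.integer(round(start / mask$step)) + 1L
  b <- a + as.integer(round(len / mask$step)) - 1L
  b <= mask$n && all(mask$valid[a:b])
}

# score one resampled channel against prepared segments/mask/baselines
scoreChannelSignal <- function(channel, segments, mask, baselines, params) {
  step <- params$rmsStep
  runs <- cellsToIntervals(mask$valid, step)
  tracks <- list()
  rawEvents <- NULL
  for (i in seq_len(nrow(runs))) {
    seg <- which(segments$start <= runs$start[i] + 1e-9 &
                   segments$end >= runs$end[i] - 1e-9)
    if (!length(seg)) next
    b <- baselines$baseline[seg[1]]
    if (is.na(b)) next
    tr <- computeRmsTrack(channel, runs$start[i], runs$end[i], params)
    if (!length(tr$values)) next
    tracks[[length(tracks) + 1L]] <- tr
    ev <- trackEvents(tr, b, params)
    rawEvents <- if (is.null(rawEvents)) ev else rbind(rawEvents, ev)
  }
  if (is.null(rawEvents))
    rawEvents <- cbind(data.frame(istart = integer(), iend = integer(),
                                  start = numeric(), end = numeric(),
                                  duration = numeric()),
                       maxAmplitude = numeric())
  rawEvents <- categorizeEvents(rawEvents[order(rawEvents$start), ,
                                          drop = FALSE], params)

  epochStarts <- remEpochStarts(segments, params$epochLen)
  valid <- vapply(epochStarts, function(s)
    allCellsValid(mask, s, params$epochLen), logical(1))
  tonic <- logical(length(epochStarts))
  coverage <- numeric(length(epochStarts))
  elevated <- rep(NA_real_, length(epochStarts))
  tonicEvents <- list()
  for (i in seq_along(epochStarts)) {
    if (!valid[i]) next
    st <- scoreTonic(rawEvents, epochStarts[i], channel, params)
    tonic[i] <- st$tonic
    coverage[i] <- st$coverage
    if (st$tonic) {
      elevated[i] <- st$elevatedBaseline
      re <- rescorePhasicInTonic(tracks, epochStarts[i],
                                 st$elevatedBaseline, params)
      tonicEvents[[as.character(epochStarts[i])]] <-
        categorizeEvents(re, params)
    }
  }
  epochTable <- data.frame(start = epochStarts, valid = valid,
                           tonic = tonic, coverage = coverage,
                           elevatedBaseline = elevated)

  nm <- as.integer(round(params$epochLen / params$miniEpochLen))
  miniStarts <- rep(epochStarts, each = nm) +
    rep((seq_len(nm) - 1L) * params$miniEpochLen, length(epochStarts))
  miniValid <- vapply(miniStarts, function(s)
    allCellsValid(mask, s, params$miniEpochLen), logical(1))
  minis <- scoreMiniEpochs(rawEvents, epochTable, params, tonicEvents,
                           miniValid)
  minis$epochTonic <- rep(epochTable$tonic & epochTable$valid, each = nm)

  # final event table: rescored events replace originals inside tonic epochs
  tonicIv <- epochTable[epochTable$tonic & epochTable$valid, , drop = FALSE]
  insideTonic <- function(s, e) {
    if (!nrow(tonicIv)) return(rep(FALSE, length(s)))
    vapply(seq_along(s), function(i)
      any(s[i] >= tonicIv$start - 1e-9 &
            e[i] <= tonicIv$start + params$epochLen + 1e-9), logical(1))
  }
  keep <- !insideTonic(rawEvents$start, rawEvents$end)
  final <- rawEvents[keep, , drop = FALSE]
  for (ev in tonicEvents) if (nrow(ev)) final <- rbind(final, ev)
  final <- final[order(final$start), c("category", "start", "end",
                                       "duration", "maxAmplitude"),
                 drop = FALSE]
  rownames(final) <- NULL
  raw <- rawEvents[, c("category", "start", "end", "duration",
                       "maxAmplitude"), drop = FALSE]
  rownames(raw) <- NULL
  list(events = final, rawEvents = raw, epochs = epochTable,
       miniEpochs = minis, tonicEvents = tonicEvents)
}

#' Score a recording for REM sleep without atonia
#'
#' Runs the full pipeline on every scoreable EMG channel: resampling to the
#' working rate, optional band filtering, REM segmentation, electrode
#' detachment detection, artefact masking, baseline estimation with
#' fallback and propagation, sliding-window RMS activity detection,
#' tonic/phasic/any classification, and per-channel plus combined-channel
#' summaries.
#'
#' @param rec a \linkS4class{RecordingSet}.
#' @param hypnogram a \linkS4class{Hypnogram}.
#' @param events list of \linkS4class{EventList} objects (arousal required
#'   by convention; respiratory and snore optional).
#' @param params a \code{\link{detectionParams}} list.
#' @param policy artefact policy: \code{"full"} excludes arousal,
#'   respiratory and snore (mentalis only) events; \code{"arousal-only"}
#'   excludes only arousals. Electrode detachment is excluded under both.
#' @param filter if \code{TRUE}, apply \code{\link{bandlimitChannel}} to
#'   each channel before scoring (for raw, unfiltered recordings).
#' @param combinations named list of combined-channel specs for
#'   \code{\link{combineChannels}}; defaults to mentalis-any + FDS-any and
#'   mentalis-any + FDS-phasic.
#' @return An \linkS4class{RswaScoring}.
#' @export
scoreRecording <- function(rec, hypnogram, events = list(),
                           params = detectionParams(),
                           policy = c("full", "arousal-only"),
                           filter = FALSE,
                           combinations = defaultCombinations()) {
  policy <- match.arg(policy)
  segments <- extractRemSegments(hypnogram, params)
  if (!nrow(segments))
    stop(errorCondition("no REM sleep in hypnogram; nothing to score",
                        class = c("rswaNoRemError", "error")))
  usedEvents <- Filter(function(ev)
    policy == "full" || eventKind(ev) == "arousal", events)

  chans <- Filter(function(ch) channelRole(ch) != "other", channels(rec))
  results <- list()
  discarded <- data.frame(channel = character(), reason = character())
  for (ch in chans) {
    role <- channelRole(ch)
    ch <- resampleChannel(ch, params$fsTarget)
    if (filter)
      ch <- bandlimitChannel(ch, params$filterHp, params$filterLp,
                             params$filterNotch)
    det <- do.call(rbind, lapply(seq_len(nrow(segments)), function(i)
      detectDetachment(ch, segments[i, ], params)))
    mask <- buildArtefactMask(segments, usedEvents, det, role,
                              recordingDuration(rec), params)
    ests <- lapply(seq_len(nrow(segments)), function(i)
      if (segments$isPeriod[i])
        estimateBaseline(ch, segments[i, ], mask, params) else NULL)
    discardedHere <- FALSE
    baselines <- withCallingHandlers(
      propagateBaseline(segments, ests, role),
      rswaChannelDiscard = function(w) {
        discardedHere <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (discardedHere) {
      discarded <- rbind(discarded,
                         data.frame(channel = role,
                                    reason = "no measurable baseline"))
      next
    }
    res <- scoreChannelSignal(ch, segments, mask, baselines, params)
    res$events <- data.frame(channel = rep(role, nrow(res$events)),
                             res$events)[
      , c("channel", "category", "start", "end", "duration",
          "maxAmplitude")]
    res$baselines <- baselines
    res$maskIntervals <- maskIntervals(mask, "artefact")
    results[[role]] <- res
  }

  summaries <- do.call(rbind, lapply(names(results), function(r)
    summarizeChannel(results[[r]][c("epochs", "miniEpochs")],
                     results[[r]]$events, r)))
  if (is.null(summaries)) summaries <- emptySummaryTable()
  miniTables <- lapply(results, `[[`, "miniEpochs")
  combined <- combineChannels(miniTables, combinations)
  new("RswaScoring", params = unclass(params), segments = segments,
      channels = results, summaries = summaries, combined = combined,
      discarded = discarded, policy = policy)
}
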