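# Core SINBAR scorer primitives: sliding-window RMS, 2x-baseline activity
# bouts, gap-merged activity events, tonic scoring with baseline elevation.

#' Compute the sliding-window RMS track of a signal stretch
#'
#' RMS of the amplitudes within 30 ms windows shifted by 15 ms, yielding
#' values at 15 ms resolution starting at \code{start}. The final partial
#' window (extending past \code{end}) is dropped.
#'
#' @param channel resampled \linkS4class{EmgChannel}.
#' @param start,end stretch to evaluate, recording-relative seconds; both
#'   must lie on the 15 ms grid.
#' @param params a \code{\link{detectionParams}} list.
#' @return An object of class \code{RmsTrack}: list with \code{values} (mV),
#'   \code{t0} (s), \code{step} (s). \code{values[i]} is the RMS over
#'   \code{[t0 + (i-1) step, t0 + (i-1) step + rmsWindow)}.
#' @export
computeRmsTrack <- function(channel, start, end,
                            params = detectionParams()) {
  step <- params$rmsStep
  w <- params$rmsWindow
  fs <- samplingRate(channel)
  nwin <- as.integer(floor(((end - w) - start) / step + 1e-9)) + 1L
  if (nwin < 1L)
    return(structure(list(values = numeric(), t0 = start, step = step),
                     class = "RmsTrack"))
  x <- samples(channel)
  cs <- c(0, cumsum(x^2))
  tk <- start + (seq_len(nwin) - 1L) * step
  lo <- as.integer(ceiling(tk * fs - 1e-9)) + 1L
  hi <- pmin(as.integer(ceiling((tk + w) * fs - 1e-9)), length(x))
  vals <- sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
  structure(list(values = vals, t0 = start, step = step),
            class = "RmsTrack")
}

#' @export
print.RmsTrack <- function(x, ...) {
  cat(sprintf("RmsTrack: %d values from %.3f s, step %g s\n",
              length(x$values), x$t0, x$step))
  invisible(x)
}

#' Flag activity bouts on an RMS track
#'
#' A 30 ms bout is an activity bout when its RMS strictly exceeds
#' \code{thresholdFactor} (2x) times the baseline amplitude; a value at
#' exactly the threshold is not activity.
#'
#' @param track an \code{RmsTrack}.
#' @param baseline baseline amplitude in mV (> 0).
#' @param params a \code{\link{detectionParams}} list.
#' @return logical vector parallel to \code{track$values}.
#' @export
detectActivityBouts <- function(track, baseline,
                                params = detectionParams()) {
  stopifnot(is.finite(baseline), baseline > 0)
  track$values > params$thresholdFactor * baseline
}

#' Merge activity bouts into increased-activity events
#'
#' Connected activity bouts spanning more than \code{minBout} (0.1 s) seed
#' an event; neighbouring activity bouts are absorbed whenever the
#' sub-threshold interruption between them is shorter than \code{maxGap}
#' (0.25 s), repeating until only interruptions of at least 0.25 s remain.
#' Flag runs never absorbed into a seeded event are discarded.
#'
#' @param flags logical activity-bout series at 15 ms resolution.
#' @param params a \code{\link{detectionParams}} list.
#' @param t0 recording time of the first flag cell, s.
#' @return data.frame with \code{istart}, \code{iend} (1-based cell indices
#'   into \code{flags}), \code{start}, \code{end}, \code{duration} (s).
#' @export
mergeIntoEvents <- function(flags, params = detectionParams(), t0 = 0) {
  step <- params$rmsStep
  empty <- data.frame(istart = integer(), iend = integer(),
                      start = numeric(), end = numeric(),
                      duration = numeric())
  if (!length(flags) || !any(flags)) return(empty)
  r <- rle(as.logical(flags))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ti <- which(r$values)                          # indices of TRUE runs
  seed <- r$lengths[ti] * step > params$minBout + 1e-9
  if (length(ti) > 1L) {
    gaps <- starts[ti[-1L]] - ends[ti[-length(ti)]] - 1L
    mergeable <- gaps * step < params$maxGap - 1e-9
    cluster <- cumsum(c(TRUE, !mergeable))
  } else cluster <- 1L
  out <- empty
  for (cl in unique(cluster)) {
    members <- ti[cluster == cl]
    if (!any(seed[cluster == cl])) next
    a <- starts[members[1L]]
    b <- ends[members[length(members)]]
    out <- rbind(out, data.frame(istart = a, iend = b,
                                 start = t0 + (a - 1L) * step,
                                 end = t0 + b * step,
                                 duration = (b - a + 1L) * step))
  }
  out
}

# detect + merge + annotate max amplitude on one track
trackEvents <- function(track, baseline, params = detectionParams()) {
  flags <- detectActivityBouts(track, baseline, params)
  ev <- mergeIntoEvents(flags, params, t0 = track$t0)
  ev$maxAmplitude <- vapply(seq_len(nrow(ev)), function(i)
    max(track$values[ev$istart[i]:ev$iend[i]]), numeric(1))
  ev
}

#' Categorize events by duration
#'
#' Phasic: 0.1 to 5.0 s (inclusive upper bound); intermediate: above 5.0 up
#' to 15 s; longer events are tonic-length.
#'
#' @param events event data.frame with a \code{duration} column.
#' @param params a \code{\link{detectionParams}} list.
#' @return \code{events} with a \code{category} column.
#' @export
categorizeEvents <- function(events, params = detectionParams()) {
  d <- events$duration
  events$category <- ifelse(d <= params$phasicMax + 1e-9, "phasic",
                     ifelse(d <= params$intermediateMax + 1e-9,
                            "intermediate", "tonic"))
  events
}

#' Score one 30-s REM epoch for tonic activity
#'
#' An epoch is tonic when increased activity covers at least 50% of its
#' span (15.0 s, inclusive). For tonic epochs the baseline is elevated to
#' the RMS of the raw signal over the union of increased-activity intervals
#' inside the epoch, against which phasic activity is then rescored.
#'
#' @param events event data.frame (\code{start}, \code{end}) for the
#'   channel, before any rescoring.
#' @param epochStart epoch start, recording-relative seconds.
#' @param channel resampled \linkS4class{EmgChannel} (for the elevated
#'   baseline RMS).
#' @param params a \code{\link{detectionParams}} list.
#' @return list with \code{tonic} (logical), \code{coverage} (s of
#'   increased activity in the epoch) and \code{elevatedBaseline} (mV, or
#'   \code{NA} when not tonic).
#' @export
scoreTonic <- function(events, epochStart, channel,
                       params = detectionParams()) {
  e0 <- epochStart
  e1 <- epochStart + params$epochLen
  s <- pmax(events$start, e0)
  e <- pmin(events$end, e1)
  keep <- e - s > 1e-12
  coverage <- sum(e[keep] - s[keep])
  tonic <- coverage >= params$tonicFraction * params$epochLen - 1e-9
  elev <- NA_real_
  if (tonic) {
    fs <- samplingRate(channel)
    x <- samples(channel)
    ssum <- 0; ncount <- 0L
    for (i in which(keep)) {
      rg <- sampleRange(s[i], e[i] - s[i], fs)
      rg[2] <- min(rg[2], length(x))
      if (rg[2] >= rg[1]) {
        ssum <- ssum + sum(x[rg[1]:rg[2]]^2)
        ncount <- ncount + (rg[2] - rg[1] + 1L)
      }
    }
    if (ncount > 0L) elev <- sqrt(ssum / ncount)
  }
  list(tonic = tonic, coverage = coverage, elevatedBaseline = elev)
}

#' Rescore phasic activity inside a tonic epoch
#'
#' Re-runs activity detection and event merging on the epoch's stretch of
#' the RMS track(s) against the elevated baseline, so that only bursts with
#' at least twice the amplitude of the tonic background survive. The tonic
#' flag of the epoch itself is unchanged; rescoring is confined to the
#' epoch's own time span.
#'
#' @param tracks list of \code{RmsTrack} objects (the channel's
#'   artefact-free REM runs).
#' @param epochStart epoch start, recording-relative seconds.
#' @param elevatedBaseline the elevated baseline amplitude, mV.
#' @param params a \code{\link{detectionParams}} list.
#' @return event data.frame (same layout as \code{\link{mergeIntoEvents}}
#'   plus \code{maxAmplitude}).
#' @export
rescorePhasicInTonic <- function(tracks, epochStart, elevatedBaseline,
                                 params = detectionParams()) {
  e0 <- epochStart
  e1 <- epochStart + params$epochLen
  out <- NULL
  for (tr in tracks) {
    if (!length(tr$values)) next
    tEnd <- tr$t0 + length(tr$values) * tr$step
    if (tr$t0 >= e1 || tEnd <= e0) next
    iLo <- max(1L, as.integer(round((e0 - tr$t0) / tr$step)) + 1L)
    iHi <- min(length(tr$values),
               as.integer(round((e1 - tr$t0) / tr$step)))
    if (iHi < iLo) next
    sub <- structure(list(values = tr$values[iLo:iHi],
                          t0 = tr$t0 + (iLo - 1L) * tr$step,
                          step = tr$step), class = "RmsTrack")
    ev <- trackEvents(sub, elevatedBaseline, params)
    out <- if (is.null(out)) ev else rbind(out, ev)
  }
  if (is.null(out))
    out <- cbind(data.frame(istart = integer(), iend = integer(),
                            start = numeric(), end = numeric(),
                            duration = numeric()),
                 maxAmplitude = numeric())
  out
}
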