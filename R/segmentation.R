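# REM segmentation and per-channel artefact masking.

#' Extract REM segments from a hypnogram
#'
#' Maximal runs of temporally contiguous REM epochs become segments. A
#' segment is a "REM period" when it holds continuous REM for at least
#' \code{minRemPeriod} (150 s); shorter runs are REM bouts, which later
#' inherit a neighbouring period's baseline amplitude.
#'
#' @param h a \linkS4class{Hypnogram}.
#' @param params a \code{\link{detectionParams}} list.
#' @return data.frame with \code{start}, \code{end} (s) and \code{isPeriod}.
#' @export
extractRemSegments <- function(h, params = detectionParams()) {
  e <- epochs(h)
  len <- epochLength(h)
  isRem <- e$stage == "REM"
  out <- data.frame(start = numeric(), end = numeric(),
                    isPeriod = logical())
  if (!any(isRem)) return(out)
  # break runs on stage change or temporal gaps between epochs
  contig <- c(TRUE, diff(e$start) <= len + 1e-9)
  runId <- cumsum(!isRem | !contig | c(TRUE, !isRem[-length(isRem)]))
  for (id in unique(runId[isRem])) {
    idx <- which(runId == id & isRem)
    s <- e$start[idx[1]]
    en <- e$start[idx[length(idx)]] + len
    out <- rbind(out, data.frame(start = s, end = en,
                                 isPeriod = (en - s) >=
                                   params$minRemPeriod - 1e-9))
  }
  out[order(out$start), , drop = FALSE]
}

#' Detect electrode detachment within a REM segment
#'
#' Stretches whose rolling RMS falls below \code{detachmentRms} (0.05 mV)
#' are treated as technical artefact (detached electrode) and excluded. The
#' rolling window is the 30 s baseline window (clamped to the segment
#' length for short bouts), stepped on the scorer's 15 ms grid; a grid cell
#' is flagged when any sub-threshold window covers it.
#'
#' @param channel resampled \linkS4class{EmgChannel}.
#' @param segment one row of \code{\link{extractRemSegments}} output (or any
#'   list with \code{start}, \code{end}).
#' @param params a \code{\link{detectionParams}} list.
#' @return data.frame of flagged intervals (\code{start}, \code{end}, s).
#' @export
detectDetachment <- function(channel, segment, params = detectionParams()) {
  step <- params$rmsStep
  fs <- samplingRate(channel)
  w <- min(params$baselineWindow, segment$end - segment$start)
  a <- as.integer(ceiling(segment$start / step - 1e-9))
  b <- as.integer(floor(segment$end / step + 1e-9)) - 1L
  t0 <- a * step
  nwin <- as.integer(floor(((segment$end - w) - t0) / step + 1e-9)) + 1L
  if (nwin < 1L)
    return(data.frame(start = numeric(), end = numeric()))
  x <- samples(channel)
  cs <- c(0, cumsum(x^2))
  tk <- t0 + (seq_len(nwin) - 1L) * step
  lo <- as.integer(ceiling(tk * fs - 1e-9)) + 1L
  hi <- pmin(as.integer(ceiling((tk + w) * fs - 1e-9)), length(x))
  rms <- sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
  winFlag <- rms < params$detachmentRms
  if (!any(winFlag))
    return(data.frame(start = numeric(), end = numeric()))
  # a cell is flagged when covered by any sub-threshold window
  wc <- as.integer(round(w / step))
  csf <- c(0, cumsum(winFlag))
  cells <- a:b
  kHi <- pmin(cells - a, nwin - 1L)
  kLo <- pmax(cells - a - wc + 1L, 0L)
  covered <- (csf[kHi + 2L] - csf[kLo + 1L]) > 0 & kHi >= kLo
  cellsToIntervals(covered, step, offset = a)
}

#' Build the per-channel artefact mask over REM sleep
#'
#' Arousal and respiratory events are excluded on every channel; snore
#' intervals only on the mentalis (chin) channel, where snoring contaminates
#' the EMG. Electrode-detachment intervals from
#' \code{\link{detectDetachment}} are excluded everywhere. Event intervals
#' partially overlapping a REM segment are clipped to it, not dropped.
#'
#' @param segments REM segment table from \code{\link{extractRemSegments}}.
#' @param events list of \linkS4class{EventList} objects.
#' @param detachment data.frame of detachment intervals (start, end).
#' @param role channel role the mask is for.
#' @param duration recording duration in seconds (defines the grid).
#' @param params a \code{\link{detectionParams}} list.
#' @return An object of class \code{ArtefactMask}: list with \code{step},
#'   \code{rem} (logical cells inside REM), \code{artefact} (logical cells
#'   masked) and \code{valid} (\code{rem & !artefact}).
#' @export
buildArtefactMask <- function(segments, events, detachment, role, duration,
                              params = detectionParams()) {
  step <- params$rmsStep
  n <- nCells(duration, step)
  rem <- intervalsToCells(segments$start, segments$end, n, step)
  art <- logical(n)
  for (ev in events) {
    if (eventKind(ev) == "snore" && role != "mentalis") next
    iv <- intervals(ev)
    if (nrow(iv)) art <- art | intervalsToCells(iv$start, iv$end, n, step)
  }
  if (!is.null(detachment) && nrow(detachment))
    art <- art | intervalsToCells(detachment$start, detachment$end, n, step)
  art <- art & rem                       # mask is defined on REM only
  structure(list(step = step, n = n, rem = rem, artefact = art,
                 valid = rem & !art),
            class = "ArtefactMask")
}

#' @export
print.ArtefactMask <- function(x, ...) {
  cat(sprintf("ArtefactMask: %.1f s REM, %.1f s masked, %.1f s valid (grid %g s)\n",
              sum(x$rem) * x$step, sum(x$artefact) * x$step,
              sum(x$valid) * x$step, x$step))
  invisible(x)
}

#' Export mask intervals as a 3-column interval table
#'
#' BED-like inspection output: one row per maximal masked interval.
#'
#' @param mask an \code{ArtefactMask}.
#' @param what \code{"artefact"}, \code{"valid"} or \code{"rem"}.
#' @return data.frame with \code{start}, \code{end} in seconds.
#' @export
maskIntervals <- function(mask, what = c("artefact", "valid", "rem")) {
  what <- match.arg(what)
  cellsToIntervals(mask[[what]], mask$step)
}
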