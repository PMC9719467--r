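# Baseline amplitude estimation per REM period, with fallback and
# propagation to REM bouts.

#' Estimate the baseline amplitude of one REM period
#'
#' The baseline amplitude is the minimum RMS over all 30 s rolling windows
#' (stepped on the 15 ms grid) that lie entirely inside the segment and are
#' continuously artefact-free on this channel. If no artefact-free 30 s
#' window exists the search is repeated with 15 s windows; if that also
#' fails the segment's baseline is reported unavailable.
#'
#' @param channel resampled \linkS4class{EmgChannel}.
#' @param segment one row of the REM segment table (needs \code{start},
#'   \code{end}).
#' @param mask the channel's \code{ArtefactMask} (see
#'   \code{\link{buildArtefactMask}}); \code{NULL} means artefact-free.
#' @param params a \code{\link{detectionParams}} list.
#' @return list with \code{amplitude} (mV, \code{NA} if unavailable) and
#'   \code{source} (\code{"window30"}, \code{"window15"} or
#'   \code{"unavailable"}).
#' @export
estimateBaseline <- function(channel, segment, mask = NULL,
                             params = detectionParams()) {
  for (w in c(params$baselineWindow, params$baselineWindowFallback)) {
    amp <- minWindowRms(channel, segment, mask, w, params)
    if (!is.na(amp)) {
      src <- if (w == params$baselineWindow) "window30" else "window15"
      return(list(amplitude = amp, source = src))
    }
  }
  list(amplitude = NA_real_, source = "unavailable")
}

minWindowRms <- function(channel, segment, mask, w, params) {
  step <- params$rmsStep
  fs <- samplingRate(channel)
  a <- as.integer(ceiling(segment$start / step - 1e-9))
  b <- as.integer(floor(segment$end / step + 1e-9)) - 1L
  if (!is.null(mask)) b <- min(b, mask$n - 1L)
  wc <- as.integer(round(w / step))
  lastStart <- b - wc + 1L
  if (lastStart < a) return(NA_real_)
  starts <- a:lastStart
  if (!is.null(mask)) {
    csv <- c(0, cumsum(mask$valid))
    ok <- (csv[starts + wc + 1L] - csv[starts + 1L]) == wc
  } else ok <- rep(TRUE, length(starts))
  if (!any(ok)) return(NA_real_)
  x <- samples(channel)
  cs <- c(0, cumsum(x^2))
  tk <- starts[ok] * step
  lo <- as.integer(ceiling(tk * fs - 1e-9)) + 1L
  hi <- pmin(as.integer(ceiling((tk + w) * fs - 1e-9)), length(x))
  keep <- lo <= hi & lo >= 1L
  if (!any(keep)) return(NA_real_)
  min(sqrt((cs[hi[keep] + 1L] - cs[lo[keep]]) / (hi[keep] - lo[keep] + 1L)))
}

#' Propagate baseline amplitudes to all REM segments
#'
#' REM periods whose own estimation failed inherit the baseline of the
#' nearest preceding period with a measured baseline, or of the following
#' one when no preceding exists. REM bouts (shorter than 150 s) take the
#' baseline of the nearest REM period, nearest by interval midpoint, ties
#' broken toward the earlier period. A channel with no measurable baseline
#' anywhere is signalled with a structured \code{rswaChannelDiscard}
#' warning, and all sources stay \code{"unavailable"}.
#'
#' @param segments REM segment table (\code{start}, \code{end},
#'   \code{isPeriod}).
#' @param estimates list of \code{\link{estimateBaseline}} results, one per
#'   segment row (entries for bouts are ignored and may be \code{NULL}).
#' @param role channel role, used in the discard warning.
#' @return data.frame: segments plus \code{baseline} (mV) and \code{source}.
#' @export
propagateBaseline <- function(segments, estimates, role = "unknown") {
  n <- nrow(segments)
  baseline <- rep(NA_real_, n)
  source <- rep("unavailable", n)
  periods <- which(segments$isPeriod)
  for (i in periods) {
    est <- estimates[[i]]
    if (!is.null(est) && !is.na(est$amplitude)) {
      baseline[i] <- est$amplitude
      source[i] <- est$source
    }
  }
  measured <- periods[!is.na(baseline[periods])]
  if (!length(measured)) {
    warningCondition(
      message = sprintf("channel '%s' discarded: no measurable baseline in any REM period",
                        role),
      class = c("rswaChannelDiscard", "warning"),
      role = role) -> cond
    warning(cond)
    return(cbind(segments, baseline = baseline, source = source))
  }
  for (i in periods) {
    if (!is.na(baseline[i])) next
    prev <- measured[measured < i]
    if (length(prev)) {
      baseline[i] <- baseline[max(prev)]
      source[i] <- "inherited_prev"
    } else {
      nxt <- min(measured[measured > i])
      baseline[i] <- baseline[nxt]
      source[i] <- "inherited_next"
    }
  }
  mids <- (segments$start + segments$end) / 2
  for (i in which(!segments$isPeriod)) {
    d <- abs(mids[periods] - mids[i])
    best <- periods[which(d <= min(d) + 1e-9)][1]   # tie -> earlier period
    baseline[i] <- baseline[best]
    source[i] <- "nearest_segment"
  }
  cbind(segments, baseline = baseline, source = source)
}
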