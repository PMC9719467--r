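#' Detection parameters for the RSWA scorer
#'
#' All numeric constants of the scoring algorithm in one validated list.
#' Defaults are the SINBAR / reference-implementation values: EMG resampled
#' to 256 Hz; RMS computed in 30 ms windows stepped by 15 ms; activity when
#' the RMS exceeds 2x the baseline amplitude; events must last more than
#' 0.1 s and end at sub-threshold interruptions of at least 0.25 s; phasic
#' events last up to 5 s, intermediate up to 15 s; an epoch is tonic when at
#' least 50% of its 30 s carry increased activity; a REM period requires
#' 150 s of continuous REM; signal with 30 s rolling RMS below 0.05 mV is
#' treated as electrode detachment; baselines are the minimum artefact-free
#' 30 s (fallback 15 s) rolling-window RMS.
#'
#' @param fsTarget working sampling rate, Hz.
#' @param rmsWindow RMS window length, s.
#' @param rmsStep RMS step (temporal resolution of the scorer), s.
#' @param thresholdFactor activity threshold as multiple of baseline.
#' @param minBout minimum duration of a seed activity run, s (strict >).
#' @param maxGap sub-threshold interruption that terminates an event, s
#'   (gaps of at least this length split events).
#' @param phasicMax maximum phasic event duration, s (inclusive).
#' @param intermediateMax maximum intermediate event duration, s (inclusive).
#' @param tonicFraction fraction of an epoch that must carry increased
#'   activity for a tonic score (inclusive bound).
#' @param epochLen sleep epoch length, s.
#' @param miniEpochLen mini-epoch length, s; must divide epochLen.
#' @param minRemPeriod minimum continuous REM for a "REM period", s.
#' @param detachmentRms rolling RMS below which signal counts as electrode
#'   detachment, mV.
#' @param baselineWindow rolling window for baseline search, s.
#' @param baselineWindowFallback fallback rolling window, s.
#' @param filterHp,filterLp,filterNotch optional pre-filter corner/notch
#'   frequencies, Hz (filtering itself is opt-in, see
#'   \code{\link{bandlimitChannel}}).
#' @return A classed list of validated parameters.
#' @examples
#' p <- detectionParams()
#' p$thresholdFactor
#' @export
detectionParams <- function(fsTarget = 256, rmsWindow = 0.030,
                            rmsStep = 0.015, thresholdFactor = 2.0,
                            minBout = 0.1, maxGap = 0.25, phasicMax = 5.0,
                            intermediateMax = 15.0, tonicFraction = 0.5,
                            epochLen = 30, miniEpochLen = 3,
                            minRemPeriod = 150, detachmentRms = 0.05,
                            baselineWindow = 30, baselineWindowFallback = 15,
                            filterHp = 10, filterLp = 100,
                            filterNotch = 50) {
  p <- list(fsTarget = fsTarget, rmsWindow = rmsWindow, rmsStep = rmsStep,
            thresholdFactor = thresholdFactor, minBout = minBout,
            maxGap = maxGap, phasicMax = phasicMax,
            intermediateMax = intermediateMax,
            tonicFraction = tonicFraction, epochLen = epochLen,
            miniEpochLen = miniEpochLen, minRemPeriod = minRemPeriod,
            detachmentRms = detachmentRms, baselineWindow = baselineWindow,
            baselineWindowFallback = baselineWindowFallback,
            filterHp = filterHp, filterLp = filterLp,
            filterNotch = filterNotch)
  durs <- c("rmsWindow", "rmsStep", "minBout", "maxGap", "phasicMax",
            "intermediateMax", "epochLen", "miniEpochLen", "minRemPeriod",
            "baselineWindow", "baselineWindowFallback")
  for (d in durs)
    if (!is.finite(p[[d]]) || p[[d]] <= 0)
      stop("parameter '", d, "' must be a positive duration")
  if (p$rmsStep > p$rmsWindow + 1e-12)
    stop("rmsStep must not exceed rmsWindow")
  if (!(p$minBout < p$phasicMax && p$phasicMax < p$intermediateMax &&
        p$intermediateMax < p$epochLen))
    stop("need minBout < phasicMax < intermediateMax < epochLen")
  if (abs(p$epochLen / p$miniEpochLen -
          round(p$epochLen / p$miniEpochLen)) > 1e-9)
    stop("miniEpochLen must divide epochLen")
  if (p$thresholdFactor <= 1)
    stop("thresholdFactor must exceed 1")
  if (p$fsTarget <= 0) stop("fsTarget must be positive")
  class(p) <- "DetectionParams"
  p
}

#' @export
print.DetectionParams <- function(x, ...) {
  cat("DetectionParams:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %g\n", nm, x[[nm]]))
  invisible(x)
}

# ---- internal time-grid helpers --------------------------------------------
# The scorer works on a global grid of rmsStep-sized cells anchored at
# recording time 0. Cell k (0-based) covers [k*step, (k+1)*step).

nCells <- function(duration, step) as.integer(floor(duration / step + 1e-9))

# logical mask over n cells marked by intervals [start, end)
intervalsToCells <- function(start, end, n, step) {
  m <- logical(n)
  for (i in seq_along(start)) {
    a <- max(0L, as.integer(floor(start[i] / step + 1e-12)))
    b <- min(n - 1L, as.integer(ceiling(end[i] / step - 1e-12)) - 1L)
    if (b >= a) m[(a + 1L):(b + 1L)] <- TRUE
  }
  m
}

# inverse: maximal runs of TRUE cells -> intervals in seconds
cellsToIntervals <- function(mask, step, offset = 0L) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = (starts[keep] + offset) * step,
             end = (ends[keep] + offset) * step)
}

# sample index range [lo, hi] (1-based) of samples with times in [t, t+w)
sampleRange <- function(t, w, fs) {
  lo <- as.integer(ceiling(t * fs - 1e-9)) + 1L
  hi <- as.integer(ceiling((t + w) * fs - 1e-9))
  c(lo, hi)
}
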