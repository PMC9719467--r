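# Resampling and optional recording-band filtering.

#' Resample an EMG channel by cubic-spline interpolation
#'
#' Signals already at the target rate are returned unchanged; otherwise the
#' samples are interpolated with a cubic spline evaluated on the target time
#' grid, passing exactly through the original sample points.
#'
#' @param channel an \linkS4class{EmgChannel}.
#' @param fsTarget target sampling rate in Hz (the scorer works at 256 Hz).
#' @return An \linkS4class{EmgChannel} at \code{fsTarget}.
#' @export
resampleChannel <- function(channel, fsTarget = 256) {
  fs <- samplingRate(channel)
  if (abs(fs - fsTarget) < 1e-9) return(channel)
  x <- samples(channel)
  if (length(x) < 4L)
    stop("too few samples to resample (need at least 4 for a cubic spline)")
  dur <- length(x) / fs
  tOld <- (seq_along(x) - 1) / fs
  tNew <- seq(0, by = 1 / fsTarget,
              length.out = as.integer(round(dur * fsTarget)))
  tNew <- tNew[tNew <= tOld[length(tOld)] + 1e-12]
  y <- stats::spline(tOld, x, xout = tNew, method = "fmm")$y
  EmgChannel(channelRole(channel), y, fsTarget)
}

#' Zero-phase band-pass (and optional notch) filtering
#'
#' Applies the recording-time filter chain (high-pass, low-pass, optional
#' mains notch) as zero-phase forward-backward Butterworth filters so that
#' burst onsets are not shifted. Filtering is opt-in: the default scoring
#' pipeline assumes input that was already filtered at acquisition time.
#'
#' @param channel an \linkS4class{EmgChannel}.
#' @param hp high-pass corner frequency, Hz.
#' @param lp low-pass corner frequency, Hz; must be below Nyquist.
#' @param notch mains notch frequency in Hz, or \code{NULL} for none.
#' @param notchHalfWidth half-width of the notch stop band, Hz.
#' @return The filtered \linkS4class{EmgChannel}.
#' @export
bandlimitChannel <- function(channel, hp = 10, lp = 100, notch = 50,
                             notchHalfWidth = 2) {
  fs <- samplingRate(channel)
  nyq <- fs / 2
  if (!(hp > 0 && hp < lp)) stop("need 0 < hp < lp")
  if (lp >= nyq) stop("low-pass corner must be below the Nyquist frequency")
  x <- samples(channel)
  bHp <- signal::butter(4, hp / nyq, type = "high")
  bLp <- signal::butter(4, lp / nyq, type = "low")
  y <- signal::filtfilt(bHp, x)
  y <- signal::filtfilt(bLp, y)
  if (!is.null(notch)) {
    if (notch + notchHalfWidth >= nyq || notch - notchHalfWidth <= 0)
      stop("notch band must lie inside (0, Nyquist)")
    bN <- signal::butter(2, c(notch - notchHalfWidth,
                              notch + notchHalfWidth) / nyq, type = "stop")
    y <- signal::filtfilt(bN, y)
  }
  EmgChannel(channelRole(channel), y, fs)
}
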