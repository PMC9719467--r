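# Independent brute-force reference implementations of the verbal scoring
# rules, written deliberately without the package's cumulative-sum or
# run-length machinery, plus small signal builders shared across tests.

# literal sliding-window RMS: select samples by time comparison, sqrt(mean)
bruteRmsTrack <- function(x, fs, t0, tEnd, window = 0.030, step = 0.015) {
  times <- (seq_along(x) - 1) / fs
  vals <- numeric(0)
  t <- t0
  while (t + window <= tEnd + 1e-9) {
    idx <- which(times >= t - 1e-12 & times < t + window - 1e-12)
    vals <- c(vals, sqrt(mean(x[idx]^2)))
    t <- t + step
  }
  vals
}

# literal event rule: seed runs strictly longer than minBout, then grow each
# seed over neighbouring activity runs while the interruption is shorter
# than maxGap, repeating to a fixed point; overlapping grown events unify.
bruteMergeEvents <- function(flags, step = 0.015, minBout = 0.1,
                             maxGap = 0.25) {
  n <- length(flags)
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (flags[i]) {
      j <- i
      while (j < n && flags[j + 1L]) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(runs)) return(data.frame(istart = integer(), iend = integer()))
  runLen <- function(r) (r[2] - r[1] + 1L) * step
  seeds <- Filter(function(r) runLen(r) > minBout + 1e-9, runs)
  if (!length(seeds)) return(data.frame(istart = integer(), iend = integer()))
  events <- list()
  for (s in seeds) {
    lo <- s[1]; hi <- s[2]
    repeat {
      changed <- FALSE
      for (r in runs) {
        if (r[2] < lo) {
          gap <- (lo - r[2] - 1L) * step
          if (gap < maxGap - 1e-9 && r[1] < lo) { lo <- r[1]; changed <- TRUE }
        }
        if (r[1] > hi) {
          gap <- (r[1] - hi - 1L) * step
          if (gap < maxGap - 1e-9 && r[2] > hi) { hi <- r[2]; changed <- TRUE }
        }
      }
      if (!changed) break
    }
    events[[length(events) + 1L]] <- c(lo, hi)
  }
  # unify events that grew into the same span
  events <- unique(events)
  events <- events[order(vapply(events, `[`, numeric(1), 1))]
  merged <- list(events[[1]])
  for (e in events[-1]) {
    last <- merged[[length(merged)]]
    if (e[1] <= last[2]) merged[[length(merged)]] <- c(last[1], max(last[2], e[2]))
    else merged[[length(merged) + 1L]] <- e
  }
  data.frame(istart = vapply(merged, `[`, numeric(1), 1),
             iend = vapply(merged, `[`, numeric(1), 2))
}

# literal full short-signal pipeline: RMS windows, strict 2x threshold,
# run/gap analysis
bruteDetect <- function(x, fs, baseline, t0 = 0,
                        tEnd = length(x) / fs,
                        thresholdFactor = 2) {
  vals <- bruteRmsTrack(x, fs, t0, tEnd)
  flags <- vals > thresholdFactor * baseline
  bruteMergeEvents(flags)
}

# band-limited Gaussian background at a target RMS (10-100 Hz at fs)
makeBandNoise <- function(n, fs = 256, rms = 0.1) {
  bf <- signal::butter(4, c(10, 100) / (fs / 2), type = "pass")
  x <- as.numeric(signal::filtfilt(bf, rnorm(n)))
  x * rms / sqrt(mean(x^2))
}

# piecewise-constant-envelope test signal: background rms plus plateaus
# given as data.frame(start, end, level) in absolute RMS units
makeLevelSignal <- function(duration, fs = 256, rms = 0.1,
                            plateaus = NULL) {
  n <- round(duration * fs)
  x <- makeBandNoise(n, fs, rms)
  if (!is.null(plateaus)) {
    t <- (seq_len(n) - 1) / fs
    for (i in seq_len(nrow(plateaus))) {
      sel <- t >= plateaus$start[i] & t < plateaus$end[i]
      x[sel] <- x[sel] * plateaus$level[i] / rms
    }
  }
  x
}

remOnlyHypnogram <- function(nEpochs, offset = 0) {
  Hypnogram(seq(offset, by = 30, length.out = nEpochs),
            rep("REM", nEpochs))
}
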