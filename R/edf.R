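# EDF / EDF+C input and output.
#
# EDF stores a 256-byte ASCII header, 256 ASCII bytes per signal, then data
# records of little-endian 16-bit integers. Physical values are recovered
# from the per-signal physical/digital calibration ranges. Only continuous
# recordings are supported; EDF+D (discontinuous) files are rejected.

edfField <- function(con, nchars) {
  raw <- readChar(con, nchars, useBytes = TRUE)
  trimws(raw)
}

edfNum <- function(con, nchars) as.numeric(edfField(con, nchars))

#' Read an EDF / EDF+C file
#'
#' Low-level reader returning every ordinary signal in its native physical
#' unit. Most callers want \code{\link{readRecording}}, which maps channels
#' to EMG roles and converts amplitudes to mV.
#'
#' @param path path to an EDF file.
#' @return list with \code{startTime} (POSIXct), \code{duration} (s) and
#'   \code{signals}: a list of \code{list(label, unit, fs, samples)}.
#' @export
readEdf <- function(path) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  version <- edfField(con, 8)
  if (version != "0") stop("not an EDF file (version field '", version, "')")
  edfField(con, 80)                      # patient id
  edfField(con, 80)                      # recording id
  startdate <- edfField(con, 8)
  starttime <- edfField(con, 8)
  edfNum(con, 8)                         # header bytes
  reserved <- edfField(con, 44)
  if (startsWith(reserved, "EDF+D"))
    stop("discontinuous EDF+ (EDF+D) recordings are not supported")
  nRecords <- edfNum(con, 8)
  recDur <- edfNum(con, 8)
  ns <- as.integer(edfNum(con, 4))
  if (is.na(ns) || ns < 1) stop("EDF header reports no signals")

  labels <- vapply(seq_len(ns), function(i) edfField(con, 16), character(1))
  for (i in seq_len(ns)) edfField(con, 80)        # transducer
  units <- vapply(seq_len(ns), function(i) edfField(con, 8), character(1))
  physMin <- vapply(seq_len(ns), function(i) edfNum(con, 8), numeric(1))
  physMax <- vapply(seq_len(ns), function(i) edfNum(con, 8), numeric(1))
  digMin <- vapply(seq_len(ns), function(i) edfNum(con, 8), numeric(1))
  digMax <- vapply(seq_len(ns), function(i) edfNum(con, 8), numeric(1))
  for (i in seq_len(ns)) edfField(con, 80)        # prefiltering
  nSamp <- vapply(seq_len(ns), function(i) as.integer(edfNum(con, 8)),
                  integer(1))
  for (i in seq_len(ns)) edfField(con, 32)        # reserved

  dmy <- as.integer(strsplit(startdate, "[.]")[[1]])
  hms <- as.integer(strsplit(starttime, "[.]")[[1]])
  year <- if (dmy[3] >= 85) 1900L + dmy[3] else 2000L + dmy[3]
  start <- as.POSIXct(sprintf("%04d-%02d-%02d %02d:%02d:%02d",
                              year, dmy[2], dmy[1], hms[1], hms[2], hms[3]),
                      tz = "UTC")

  perRecord <- sum(nSamp)
  data <- readBin(con, "integer", n = nRecords * perRecord, size = 2,
                  signed = TRUE, endian = "little")
  if (length(data) < nRecords * perRecord)
    stop("EDF file truncated: expected ", nRecords * perRecord,
         " samples, got ", length(data))
  offsets <- cumsum(c(0L, nSamp))
  signals <- vector("list", ns)
  for (i in seq_len(ns)) {
    if (grepl("EDF Annotations", labels[i], fixed = TRUE)) next
    idx <- as.vector(outer(offsets[i] + seq_len(nSamp[i]),
                           (seq_len(nRecords) - 1L) * perRecord, `+`))
    gain <- (physMax[i] - physMin[i]) / (digMax[i] - digMin[i])
    x <- (data[idx] - digMin[i]) * gain + physMin[i]
    signals[[i]] <- list(label = labels[i], unit = units[i],
                         fs = nSamp[i] / recDur, samples = x)
  }
  signals <- signals[!vapply(signals, is.null, logical(1))]
  list(startTime = start, duration = nRecords * recDur, signals = signals)
}

unitToMv <- function(unit) {
  u <- trimws(unit)
  if (u %in% c("uV", "µV", "\xb5V", "microV")) return(1e-3)
  if (u %in% c("mV", "")) return(1)
  if (u == "V") return(1e3)
  warning("unknown EDF physical dimension '", u, "'; assuming mV")
  1
}

#' Read an EDF recording and map channels to EMG roles
#'
#' @param path path to a continuous EDF/EDF+C file.
#' @param channelMap named character vector mapping raw EDF signal labels to
#'   roles in \code{\link{EMG_ROLES}} (e.g.
#'   \code{c("EMG Chin" = "mentalis")}). Unmapped signals are dropped.
#' @param requireAll error when a mapped label is absent from the file.
#'   Defaults to \code{TRUE} for an explicit map; with the default map,
#'   absent labels are silently skipped.
#' @return A \linkS4class{RecordingSet} with amplitudes in mV.
#' @seealso \code{\link{defaultChannelMap}}
#' @export
readRecording <- function(path, channelMap = defaultChannelMap(),
                          requireAll = !missing(channelMap)) {
  edf <- readEdf(path)
  labels <- vapply(edf$signals, `[[`, character(1), "label")
  missing <- setdiff(names(channelMap), labels)
  if (length(missing)) {
    if (requireAll)
      stop("mapped channel(s) absent from EDF: ",
           paste(missing, collapse = ", "))
    channelMap <- channelMap[!names(channelMap) %in% missing]
  }
  chans <- list()
  for (lab in names(channelMap)) {
    sig <- edf$signals[[match(lab, labels)]]
    chans[[length(chans) + 1L]] <-
      EmgChannel(channelMap[[lab]], sig$samples * unitToMv(sig$unit),
                 sig$fs)
  }
  RecordingSet(chans, edf$startTime, edf$duration)
}

#' Default raw-label to role channel map
#'
#' The labels written by \code{\link{generateFixture}}; real recordings
#' usually need an explicit map.
#' @return named character vector usable as \code{channelMap}.
#' @export
defaultChannelMap <- function() {
  c("EMG Ment" = "mentalis", "EMG FDS li" = "fds_left",
    "EMG FDS re" = "fds_right", "EMG Tib li" = "ta_left",
    "EMG Tib re" = "ta_right")
}

padField <- function(x, n) {
  x <- as.character(x)
  if (nchar(x, type = "bytes") > n) x <- substr(x, 1, n)
  formatC(x, width = -n)
}

#' Write a RecordingSet to an EDF file
#'
#' Writes plain continuous EDF with one-second data records, mV physical
#' dimension and symmetric 16-bit calibration per channel. Sampling rates
#' must be integer and the duration a whole number of seconds.
#'
#' @param rec a \linkS4class{RecordingSet}.
#' @param path output path.
#' @param labels optional character vector of raw labels, one per channel;
#'   defaults to labels matching \code{\link{defaultChannelMap}}.
#' @return \code{path}, invisibly.
#' @export
writeRecording <- function(rec, path, labels = NULL) {
  chans <- channels(rec)
  ns <- length(chans)
  if (is.null(labels)) {
    map <- defaultChannelMap()
    labels <- vapply(chans, function(ch) {
      hit <- names(map)[match(channelRole(ch), map)]
      if (is.na(hit)) channelRole(ch) else hit
    }, character(1))
  }
  nRecords <- as.integer(round(recordingDuration(rec)))
  if (abs(nRecords - recordingDuration(rec)) > 1e-9)
    stop("duration must be a whole number of seconds for EDF output")
  fs <- vapply(chans, samplingRate, numeric(1))
  if (any(abs(fs - round(fs)) > 1e-9))
    stop("sampling rates must be integer for EDF output")

  physMax <- vapply(chans, function(ch) {
    m <- max(abs(samples(ch)), 1e-6) * 1.02
    # round so the value survives the 8-char ASCII header field exactly
    as.numeric(sprintf("%.5g", m))
  }, numeric(1))

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, n) writeChar(padField(x, n), con, eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)
  wr("Startdate X X X X", 80)
  wr(format(startTime(rec), "%d.%m.%y"), 8)
  wr(format(startTime(rec), "%H.%M.%S"), 8)
  wr(as.character(256L * (ns + 1L)), 8)
  wr("EDF+C", 44)
  wr(as.character(nRecords), 8)
  wr("1", 8)
  wr(as.character(ns), 4)
  for (lab in labels) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("mV", 8)
  for (i in seq_len(ns)) wr(sprintf("%.5g", -physMax[i]), 8)
  for (i in seq_len(ns)) wr(sprintf("%.5g", physMax[i]), 8)
  for (i in seq_len(ns)) wr("-32767", 8)
  for (i in seq_len(ns)) wr("32767", 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(as.character(round(fs[i])), 8)
  for (i in seq_len(ns)) wr("", 32)

  dig <- lapply(seq_len(ns), function(i) {
    x <- samples(chans[[i]])
    need <- nRecords * round(fs[i])
    if (length(x) < need) x <- c(x, numeric(need - length(x)))
    as.integer(pmax(-32767L, pmin(32767L, round(x / physMax[i] * 32767))))
  })
  block <- integer(0)
  spr <- as.integer(round(fs))
  out <- vector("list", nRecords)
  for (r in seq_len(nRecords)) {
    rec_i <- lapply(seq_len(ns), function(i)
      dig[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])])
    out[[r]] <- unlist(rec_i)
  }
  writeBin(unlist(out), con, size = 2, endian = "little")
  invisible(path)
}
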