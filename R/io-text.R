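# Plain-text hypnogram and event-list parsing.
#
# Sleep laboratories export these files in vendor-specific dialects; the
# shipped default is a best-effort reconstruction of a common export
# layout ("HH:MM:SS,fff; STAGE" per 30-s epoch; event lines
# "HH:MM:SS,fff-HH:MM:SS,fff; LABEL"). Everything about the dialect is
# declarative configuration, not code: timestamp format, separator, and the
# stage vocabulary (matched case-insensitively).

#' Text dialect for hypnogram and event files
#'
#' @param sep field separator between timestamp(s) and label.
#' @param rangeSep separator between start and end timestamps on event
#'   lines.
#' @param decimal decimal mark inside timestamps (vendor exports often use a
#'   comma for milliseconds).
#' @param stageVocab named character vector mapping stage tokens
#'   (case-insensitive) to the internal vocabulary
#'   \code{\link{SLEEP_STAGES}}; unknown tokens become \code{"UNSCORED"}.
#' @return classed list describing the dialect.
#' @export
profileDialect <- function(sep = ";", rangeSep = "-", decimal = ",",
                           stageVocab = c(
                             "W" = "W", "WAKE" = "W", "WK" = "W",
                             "N1" = "N1", "S1" = "N1",
                             "N2" = "N2", "S2" = "N2",
                             "N3" = "N3", "N4" = "N3", "S3" = "N3",
                             "S4" = "N3", "SWS" = "N3",
                             "REM" = "REM", "R" = "REM",
                             "A" = "UNSCORED", "ARTEFACT" = "UNSCORED",
                             "ARTIFACT" = "UNSCORED", "MT" = "UNSCORED",
                             "UNSCORED" = "UNSCORED")) {
  structure(list(sep = sep, rangeSep = rangeSep, decimal = decimal,
                 stageVocab = stageVocab),
            class = "ProfileDialect")
}

# "HH:MM:SS,fff" (or with '.') -> seconds of day
clockToSeconds <- function(x, decimal = ",") {
  x <- trimws(x)
  x <- gsub(decimal, ".", x, fixed = TRUE)
  parts <- strsplit(x, ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 3L || anyNA(suppressWarnings(as.numeric(p))))
      return(NA_real_)
    as.numeric(p[1]) * 3600 + as.numeric(p[2]) * 60 + as.numeric(p[3])
  }, numeric(1))
}

secondsToClock <- function(s, decimal = ",") {
  s <- round(s, 3)
  h <- floor(s / 3600) %% 24
  m <- floor((s %% 3600) / 60)
  sec <- s %% 60
  out <- sprintf("%02d:%02d:%06.3f", h, m, sec)
  gsub(".", decimal, out, fixed = TRUE)
}

# clock seconds-of-day -> recording-relative seconds, wrapping past midnight
relativeToStart <- function(clockSec, startTime) {
  s0 <- as.numeric(difftime(startTime, trunc(startTime, "days"),
                            units = "secs"))
  rel <- clockSec - s0
  rel[!is.na(rel) & rel < -1e-9] <- rel[!is.na(rel) & rel < -1e-9] + 86400
  rel
}

#' Parse a plain-text sleep profile into a Hypnogram
#'
#' One line per 30-s epoch: a clock timestamp, the dialect separator, and a
#' stage token. Tokens are matched case-insensitively against the dialect's
#' stage vocabulary; unknown tokens map to \code{"UNSCORED"}.
#'
#' @param path path to the sleep-profile text file.
#' @param startTime POSIXct recording start used to convert clock times to
#'   recording-relative seconds (wrapping once past midnight).
#' @param dialect a \code{\link{profileDialect}}.
#' @param epochLength epoch length in seconds.
#' @return A \linkS4class{Hypnogram}.
#' @export
parseSleepProfile <- function(path, startTime,
                              dialect = profileDialect(),
                              epochLength = 30) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty sleep profile: ", path)
  fields <- strsplit(lines, dialect$sep, fixed = TRUE)
  starts <- numeric(length(lines))
  stages <- character(length(lines))
  vocab <- dialect$stageVocab
  names(vocab) <- toupper(names(vocab))
  for (i in seq_along(lines)) {
    f <- fields[[i]]
    if (length(f) < 2L)
      stop("sleep profile parse error at line ", i, ": '", lines[i], "'")
    sec <- clockToSeconds(f[1], dialect$decimal)
    if (is.na(sec))
      stop("sleep profile parse error at line ", i, ": bad timestamp '",
           trimws(f[1]), "'")
    starts[i] <- sec
    token <- toupper(trimws(paste(f[-1], collapse = dialect$sep)))
    stages[i] <- if (token %in% names(vocab)) vocab[[token]] else "UNSCORED"
  }
  Hypnogram(relativeToStart(starts, startTime), stages, epochLength)
}

#' Serialize a Hypnogram to the profile text dialect
#'
#' Inverse of \code{\link{parseSleepProfile}} for the same dialect.
#'
#' @param h a \linkS4class{Hypnogram}.
#' @param path output path.
#' @param startTime POSIXct recording start.
#' @param dialect a \code{\link{profileDialect}}.
#' @return \code{path}, invisibly.
#' @export
writeSleepProfile <- function(h, path, startTime,
                              dialect = profileDialect()) {
  s0 <- as.numeric(difftime(startTime, trunc(startTime, "days"),
                            units = "secs"))
  e <- epochs(h)
  lines <- sprintf("%s%s %s", secondsToClock(s0 + e$start, dialect$decimal),
                   dialect$sep, as.character(e$stage))
  writeLines(lines, path)
  invisible(path)
}

#' Parse a plain-text event list
#'
#' One event per line: start timestamp, then either an end timestamp
#' (separated by the dialect's \code{rangeSep}) or, after the field
#' separator, a duration in seconds; an optional trailing label field is
#' ignored. Empty files are valid and mean "no events of this kind".
#'
#' @param path path to the event text file.
#' @param kind event kind: \code{"arousal"}, \code{"respiratory"} or
#'   \code{"snore"}.
#' @param startTime POSIXct recording start.
#' @param dialect a \code{\link{profileDialect}}.
#' @return An \linkS4class{EventList} in recording-relative seconds, sorted.
#' @export
parseEvents <- function(path, kind, startTime,
                        dialect = profileDialect()) {
  lines <- if (file.exists(path)) readLines(path, warn = FALSE) else
    stop("event file not found: ", path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- ends <- numeric(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], dialect$sep, fixed = TRUE)[[1]]
    tspan <- strsplit(f[1], dialect$rangeSep, fixed = TRUE)[[1]]
    s <- clockToSeconds(tspan[1], dialect$decimal)
    if (is.na(s))
      stop("event parse error at line ", i, ": bad timestamp '",
           trimws(tspan[1]), "'")
    if (length(tspan) >= 2L) {
      e <- clockToSeconds(tspan[2], dialect$decimal)
      if (is.na(e))
        stop("event parse error at line ", i, ": bad end timestamp")
      if (e < s) e <- e + 86400          # event crossing midnight
    } else {
      if (length(f) < 2L)
        stop("event parse error at line ", i,
             ": need end timestamp or duration")
      dur <- suppressWarnings(as.numeric(gsub(dialect$decimal, ".",
                                              trimws(f[2]), fixed = TRUE)))
      if (is.na(dur))
        stop("event parse error at line ", i, ": bad duration '",
             trimws(f[2]), "'")
      if (dur < 0)
        stop("event parse error at line ", i, ": negative duration")
      e <- s + dur
    }
    starts[i] <- s; ends[i] <- e
  }
  rs <- relativeToStart(starts, startTime)
  EventList(kind, rs, rs + (ends - starts))
}

#' Serialize an EventList to the event text dialect
#'
#' @param ev an \linkS4class{EventList}.
#' @param path output path.
#' @param startTime POSIXct recording start.
#' @param dialect a \code{\link{profileDialect}}.
#' @return \code{path}, invisibly.
#' @export
writeEvents <- function(ev, path, startTime, dialect = profileDialect()) {
  s0 <- as.numeric(difftime(startTime, trunc(startTime, "days"),
                            units = "secs"))
  iv <- intervals(ev)
  lines <- sprintf("%s%s%s%s %s",
                   secondsToClock(s0 + iv$start, dialect$decimal),
                   dialect$rangeSep,
                   secondsToClock(s0 + iv$end, dialect$decimal),
                   dialect$sep, eventKind(ev))
  writeLines(lines, path)
  invisible(path)
}
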