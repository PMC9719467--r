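# Tabular outputs: event timestamp CSV and the two summary tables.

#' Write the scorer's output files
#'
#' Writes three spreadsheet-compatible tables: (1) the event CSV with one
#' row per increased-activity event (channel, category, start, end,
#' duration in s, maximum RMS amplitude in mV; timestamps at millisecond
#' precision), (2) the per-channel summary (tonic/phasic/any counts and
#' percentages of artefact-free REM (mini-)epochs, bout means, and total
#' (mini-)epoch counts with and without artefacts), and (3) the
#' combined-channel percentages.
#'
#' @param scoring an \linkS4class{RswaScoring}.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return named character vector of the three file paths, invisibly.
#' @export
writeOutputs <- function(scoring, dir, prefix = "rswa") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  evPath <- file.path(dir, paste0(prefix, "_events.csv"))
  chPath <- file.path(dir, paste0(prefix, "_channel_summary.csv"))
  coPath <- file.path(dir, paste0(prefix, "_combined_summary.csv"))

  ev <- rswaEvents(scoring)
  evOut <- data.frame(channel = ev$channel, category = ev$category,
                      start = sprintf("%.3f", ev$start),
                      end = sprintf("%.3f", ev$end),
                      duration = sprintf("%.3f", ev$duration),
                      maxAmplitude = sprintf("%.9f", ev$maxAmplitude))
  utils::write.csv(evOut, evPath, row.names = FALSE, quote = FALSE)
  utils::write.csv(channelSummary(scoring), chPath, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(combinedSummary(scoring), coPath, row.names = FALSE,
                   quote = FALSE)
  invisible(c(events = evPath, channels = chPath, combined = coPath))
}

#' Read an event CSV back into a data.frame
#'
#' Inverse of the event table written by \code{\link{writeOutputs}}; numeric
#' columns are restored so that a written-then-read table equals the
#' in-memory one at the serialized precision.
#'
#' @param path path to the event CSV.
#' @return data.frame with the event-table columns.
#' @export
readEventTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cl in c("start", "end", "duration", "maxAmplitude"))
    df[[cl]] <- as.numeric(df[[cl]])
  df
}
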