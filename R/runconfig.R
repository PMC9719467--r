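# End-to-end run driver for file-based scoring runs.

#' Read a YAML/JSON run configuration
#'
#' Recognised keys: \code{edf}, \code{hypnogram}, \code{events} (named
#' paths: \code{arousal}, \code{respiratory}, \code{snore}),
#' \code{channel_map} (raw label to role), \code{params} (overrides for
#' \code{\link{detectionParams}}), \code{policy}, \code{filter},
#' \code{combinations}, \code{output_dir}.
#'
#' @param path path to a YAML (or JSON) configuration file.
#' @return the configuration as a list.
#' @export
readRunConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read run configurations")
  yaml::read_yaml(path)
}

#' Run a complete file-based scoring
#'
#' Reads the EDF recording, hypnogram and event files named in the
#' configuration, scores the recording with \code{\link{scoreRecording}},
#' writes the three output tables, and logs every discarded channel and the
#' per-segment baseline sources to \code{stderr}.
#'
#' @param config configuration list (see \code{\link{readRunConfig}}).
#' @return the \linkS4class{RswaScoring}, invisibly. Raises classed errors
#'   \code{rswaNoRemError} (no REM sleep), \code{rswaNoChannelError} (all
#'   channels discarded) or ordinary parse errors, which the command-line
#'   wrapper maps to distinct exit codes.
#' @export
runScoring <- function(config) {
  for (key in c("edf", "hypnogram"))
    if (is.null(config[[key]]) || !file.exists(config[[key]]))
      stop("configuration must name an existing '", key, "' file")
  cmap <- if (!is.null(config$channel_map))
    unlist(config$channel_map) else defaultChannelMap()
  rec <- readRecording(config$edf, cmap,
                       requireAll = !is.null(config$channel_map))
  params <- do.call(detectionParams, as.list(config$params))
  hyp <- parseSleepProfile(config$hypnogram, startTime(rec))
  events <- list()
  for (kind in intersect(names(config$events), EVENT_KINDS))
    events[[kind]] <- parseEvents(config$events[[kind]], kind,
                                  startTime(rec))
  policy <- if (is.null(config$policy)) "full" else config$policy
  combos <- if (is.null(config$combinations)) defaultCombinations() else
    lapply(config$combinations, unlist)
  scoring <- scoreRecording(rec, hyp, events, params, policy = policy,
                            filter = isTRUE(config$filter),
                            combinations = combos)
  disc <- discardedChannels(scoring)
  for (i in seq_len(nrow(disc)))
    message(sprintf("discarded channel %s: %s", disc$channel[i],
                    disc$reason[i]))
  if (!length(scoring@channels))
    stop(errorCondition("no scoreable channel remains",
                        class = c("rswaNoChannelError", "error")))
  bt <- baselineTable(scoring)
  for (i in seq_len(nrow(bt)))
    message(sprintf("baseline %s [%g, %g): %.5f mV (%s)", bt$channel[i],
                    bt$start[i], bt$end[i], bt$baseline[i], bt$source[i]))
  s <- channelSummary(scoring)
  for (i in seq_len(nrow(s)))
    message(sprintf("channel %s: %d/%d valid epochs, %d/%d valid mini-epochs",
                    s$channel[i], s$nEpochsValid[i], s$nEpochsTotal[i],
                    s$nMiniValid[i], s$nMiniTotal[i]))
  outDir <- if (is.null(config$output_dir)) "." else config$output_dir
  writeOutputs(scoring, outDir)
  invisible(scoring)
}
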