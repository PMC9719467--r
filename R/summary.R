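# Per-channel and combined-channel RSWA summary metrics.

emptySummaryTable <- function() {
  data.frame(channel = character(), nEpochsTotal = integer(),
             nEpochsValid = integer(), nMiniTotal = integer(),
             nMiniValid = integer(), nTonic = integer(),
             nPhasic = integer(), nAny = integer(), pctTonic = numeric(),
             pctPhasic = numeric(), pctAny = numeric(),
             meanMaxAmplitudePhasic = numeric(),
             meanDurationPhasic = numeric(),
             meanMaxAmplitudeAny = numeric(), meanDurationAny = numeric())
}

#' Summarize one channel's RSWA scoring
#'
#' Counts and percentages of tonic 30-s epochs and phasic/any 3-s
#' mini-epochs relative to the channel's artefact-free REM (mini-)epochs,
#' plus arithmetic means of the maximum amplitude and duration of phasic
#' bouts and of "any" bouts (phasic and intermediate pooled; tonic
#' stretches are not bouts and enter no mean).
#'
#' @param scores list with \code{epochs} and \code{miniEpochs} tables, as in
#'   \code{\link{scoreTable}}.
#' @param events the channel's final event table (with \code{category}).
#' @param role channel role label.
#' @return one-row data.frame; percentages are \code{NA} (with a structured
#'   \code{rswaEmptyDenominator} warning) when no valid (mini-)epochs exist.
#' @export
summarizeChannel <- function(scores, events, role) {
  ep <- scores$epochs
  mi <- scores$miniEpochs
  nEpV <- sum(ep$valid)
  nMiV <- sum(mi$valid)
  nTonic <- sum(ep$tonic & ep$valid)
  nPhasic <- sum(mi$phasic & mi$valid)
  nAny <- sum(mi$any & mi$valid)
  if (nMiV == 0L || nEpV == 0L)
    warning(warningCondition(
      sprintf("channel '%s': no valid (mini-)epochs; percentages undefined",
              role),
      class = c("rswaEmptyDenominator", "warning"), role = role))
  pct <- function(k, n) if (n > 0L) 100 * k / n else NA_real_
  phasicEv <- events[events$category == "phasic", , drop = FALSE]
  anyEv <- events[events$category %in% c("phasic", "intermediate"), ,
                  drop = FALSE]
  mstat <- function(x) if (length(x)) mean(x) else NA_real_
  data.frame(channel = role,
             nEpochsTotal = nrow(ep), nEpochsValid = nEpV,
             nMiniTotal = nrow(mi), nMiniValid = nMiV,
             nTonic = nTonic, nPhasic = nPhasic, nAny = nAny,
             pctTonic = pct(nTonic, nEpV),
             pctPhasic = pct(nPhasic, nMiV),
             pctAny = pct(nAny, nMiV),
             meanMaxAmplitudePhasic = mstat(phasicEv$maxAmplitude),
             meanDurationPhasic = mstat(phasicEv$duration),
             meanMaxAmplitudeAny = mstat(anyEv$maxAmplitude),
             meanDurationAny = mstat(anyEv$duration))
}

#' Default combined-channel specifications
#'
#' The two combinations reported by the scorer: chin "any" together with
#' bilateral FDS "any", and chin "any" together with bilateral FDS
#' "phasic".
#'
#' @return named list of character vectors of \code{"role:category"} tokens.
#' @export
defaultCombinations <- function() {
  list("mentalis_any+fds_any" =
         c("mentalis:any", "fds_left:any", "fds_right:any"),
       "mentalis_any+fds_phasic" =
         c("mentalis:any", "fds_left:phasic", "fds_right:phasic"))
}

#' Combined-channel RSWA percentages
#'
#' A mini-epoch is positive for a combination when it is positive for any
#' listed (role, category) term; the denominator is the set of mini-epochs
#' valid in all listed channels, so every counted mini-epoch is assessable
#' on every constituent channel. A combination naming a channel that was
#' not scored (e.g. discarded during baseline estimation) is reported as
#' unavailable (\code{NA}).
#'
#' @param miniTables named list (by role) of mini-epoch tables as produced
#'   by scoring (\code{start}, \code{valid}, \code{phasic}, \code{any}).
#' @param combinations named list of character vectors of
#'   \code{"role:category"} tokens; \code{"fds"} and \code{"ta"} expand to
#'   both sides.
#' @return data.frame with \code{combination}, \code{nValid},
#'   \code{nPositive}, \code{pct}, \code{available}.
#' @export
combineChannels <- function(miniTables, combinations = defaultCombinations()) {
  out <- data.frame(combination = character(), nValid = integer(),
                    nPositive = integer(), pct = numeric(),
                    available = logical())
  for (nm in names(combinations)) {
    terms <- lapply(combinations[[nm]], function(tok) {
      p <- strsplit(tok, ":", fixed = TRUE)[[1]]
      if (length(p) != 2L || !p[2] %in% c("phasic", "any", "tonic"))
        stop("bad combination token: ", tok)
      roles <- switch(p[1],
                      fds = c("fds_left", "fds_right"),
                      ta = c("ta_left", "ta_right"),
                      p[1])
      lapply(roles, function(r) c(role = r, cat = p[2]))
    })
    terms <- do.call(c, terms)
    roles <- unique(vapply(terms, `[[`, character(1), "role"))
    if (!all(roles %in% names(miniTables))) {
      out <- rbind(out, data.frame(combination = nm, nValid = NA_integer_,
                                   nPositive = NA_integer_,
                                   pct = NA_real_, available = FALSE))
      next
    }
    ref <- miniTables[[roles[1]]]$start
    validAll <- rep(TRUE, length(ref))
    positive <- rep(FALSE, length(ref))
    for (r in roles) {
      tb <- miniTables[[r]]
      idx <- match(round(ref / 3), round(tb$start / 3))
      validAll <- validAll & !is.na(idx) & tb$valid[idx]
    }
    for (tm in terms) {
      tb <- miniTables[[tm[["role"]]]]
      idx <- match(round(ref / 3), round(tb$start / 3))
      flag <- if (tm[["cat"]] == "any") tb$any[idx] else
        if (tm[["cat"]] == "phasic") tb$phasic[idx] else
          tb$epochTonic[idx]
      positive <- positive | (validAll & !is.na(flag) & flag)
    }
    nV <- sum(validAll)
    nP <- sum(positive & validAll)
    out <- rbind(out, data.frame(combination = nm, nValid = nV,
                                 nPositive = nP,
                                 pct = if (nV > 0) 100 * nP / nV else
                                   NA_real_,
                                 available = TRUE))
  }
  out
}
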