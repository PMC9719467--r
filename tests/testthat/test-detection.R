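# Core scorer: RMS track, activity bouts, event merging, tonic scoring.

params <- detectionParams()

track <- function(values, t0 = 0, step = 0.015) {
  structure(list(values = values, t0 = t0, step = step), class = "RmsTrack")
}

emptyEv <- function() data.frame(start = numeric(), end = numeric(),
                                 duration = numeric())

test_that("RMS track reproduces closed-form values on analytic signals", {
  fs <- 256
  const <- EmgChannel("mentalis", rep(0.02, fs * 2), fs)
  tr <- computeRmsTrack(const, 0, 2, params)
  expect_equal(length(tr$values),
               floor((2 - params$rmsWindow) / params$rmsStep) + 1)
  expect_true(all(abs(tr$values - 0.02) < 1e-12))

  sq <- EmgChannel("mentalis", rep(c(0.05, -0.05), fs), fs)
  trSq <- computeRmsTrack(sq, 0, 2, params)
  expect_true(all(abs(trSq$values - 0.05) < 1e-12))

  # 25 Hz sine with windows spanning whole periods: RMS = A / sqrt(2)
  A <- 0.3
  fsS <- 1000                      # 40 ms window = one exact 25 Hz period
  tt <- (0:(fsS * 2 - 1)) / fsS
  sine <- EmgChannel("mentalis", A * sin(2 * pi * 25 * tt), fsS)
  pWhole <- detectionParams(rmsWindow = 0.040, rmsStep = 0.020)
  trS <- computeRmsTrack(sine, 0, 2, pWhole)
  expect_true(all(abs(trS$values - A / sqrt(2)) < 0.02 * A / sqrt(2)))
})

test_that("RMS track agrees with the literal window-by-window oracle", {
  set.seed(11)
  fs <- 256
  x <- makeBandNoise(fs * 3, fs, 0.1)
  ch <- EmgChannel("mentalis", x, fs)
  tr <- computeRmsTrack(ch, 0, 3, params)
  ref <- bruteRmsTrack(x, fs, 0, 3)
  expect_equal(tr$values, ref, tolerance = 1e-12)
  # track starting mid-signal, on the 15 ms grid
  tr2 <- computeRmsTrack(ch, 0.45, 2.1, params)
  ref2 <- bruteRmsTrack(x, fs, 0.45, 2.1)
  expect_equal(tr2$values, ref2, tolerance = 1e-12)
})

test_that("empty track for stretches shorter than one window", {
  ch <- EmgChannel("mentalis", rep(0.1, 256), 256)
  expect_length(computeRmsTrack(ch, 0, 0.015, params)$values, 0)
})

test_that("activity threshold is strict: exactly 2x baseline is no bout", {
  tr <- track(c(0.015, 0.025, 0.025, 0.019, 0.020))
  expect_identical(detectActivityBouts(tr, 0.01, params),
                   c(FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_false(any(detectActivityBouts(track(rep(0.019, 10)), 0.01,
                                       params)))
  expect_error(detectActivityBouts(tr, 0, params))
})

test_that("event merging follows the seed / gap-extension rule", {
  mk <- function(...) {
    runs <- list(...)
    f <- logical(0)
    for (r in runs) f <- c(f, rep(r[1] > 0, r[2]))
    f
  }
  # 6 cells = 0.09 s: not longer than 0.1 s, no event
  expect_equal(nrow(mergeIntoEvents(mk(c(1, 6)), params)), 0)
  # 7 cells = 0.105 s: seeds an event
  ev <- mergeIntoEvents(mk(c(1, 7)), params)
  expect_equal(ev$duration, 7 * 0.015)
  # 13-cell gap (0.195 s < 0.25) merges two seed runs into one event
  ev <- mergeIntoEvents(mk(c(1, 13), c(0, 13), c(1, 13)), params)
  expect_equal(nrow(ev), 1)
  expect_equal(c(ev$istart, ev$iend), c(1, 39))
  # 20-cell gap (0.30 s >= 0.25) keeps them apart
  ev <- mergeIntoEvents(mk(c(1, 13), c(0, 20), c(1, 13)), params)
  expect_equal(nrow(ev), 2)
  # 17-cell gap (0.255 s) also splits; 16 cells (0.24 s) merges
  expect_equal(nrow(mergeIntoEvents(mk(c(1, 13), c(0, 17), c(1, 13)),
                                    params)), 2)
  expect_equal(nrow(mergeIntoEvents(mk(c(1, 13), c(0, 16), c(1, 13)),
                                    params)), 1)
  # a short satellite run is absorbed across a small gap
  ev <- mergeIntoEvents(mk(c(1, 13), c(0, 5), c(1, 2)), params)
  expect_equal(c(ev$istart, ev$iend), c(1, 20))
  # runs without any seed never form an event, even if merged span > 0.1 s
  expect_equal(nrow(mergeIntoEvents(mk(c(1, 5), c(0, 3), c(1, 5)),
                                    params)), 0)
})

test_that("event merging equals the brute-force reference on random flags", {
  set.seed(21)
  for (rep in 1:300) {
    n <- sample(20:200, 1)
    flags <- runif(n) < runif(1, 0.2, 0.8)
    got <- mergeIntoEvents(flags, params)
    ref <- bruteMergeEvents(flags)
    expect_equal(got$istart, ref$istart)
    expect_equal(got$iend, ref$iend)
  }
})

test_that("tonic rule: >= 15 s of increased activity in a 30-s epoch", {
  fs <- 256
  ch <- EmgChannel("mentalis", rep(0.08, fs * 30), fs)
  mkev <- function(...) {
    iv <- list(...)
    data.frame(start = vapply(iv, `[`, numeric(1), 1),
               end = vapply(iv, `[`, numeric(1), 2))
  }
  expect_false(scoreTonic(mkev(c(2, 16)), 0, ch, params)$tonic)   # 14 s
  expect_true(scoreTonic(mkev(c(2, 17)), 0, ch, params)$tonic)    # 15 s
  expect_true(scoreTonic(mkev(c(2, 18)), 0, ch, params)$tonic)    # 16 s
  # three 5.5 s events: 16.5 s in total, none individually >= 15 s
  st <- scoreTonic(mkev(c(1, 6.5), c(10, 15.5), c(20, 25.5)), 0, ch,
                   params)
  expect_true(st$tonic)
  # constant signal: elevated baseline equals the signal level
  expect_equal(st$elevatedBaseline, 0.08, tolerance = 1e-9)
})

test_that("coverage clipping at epoch edges is exact", {
  fs <- 256
  ch <- EmgChannel("mentalis", rep(0.08, fs * 30), fs)
  st <- scoreTonic(data.frame(start = c(-10, 25), end = c(10, 40)), 0, ch,
                   params)
  expect_equal(st$coverage, 15)
  expect_true(st$tonic)
})

test_that("phasic rescoring inside a tonic epoch uses the elevated baseline", {
  fs <- 256
  b <- 0.05
  # plateau at 3b across the whole epoch, with a 1 s burst at 9b (3x the
  # plateau) and a 1 s burst at 4.5b (1.5x the plateau)
  lvl <- rep(3 * b, fs * 30)
  tt <- (seq_along(lvl) - 1) / fs
  lvl[tt >= 10 & tt < 11] <- 9 * b
  lvl[tt >= 20 & tt < 21] <- 4.5 * b
  ch <- EmgChannel("mentalis", lvl, fs)
  tr <- computeRmsTrack(ch, 0, 30, params)
  ev <- mergeIntoEvents(detectActivityBouts(tr, b, params), params)
  expect_equal(nrow(ev), 1)                # one wall-to-wall event
  st <- scoreTonic(data.frame(start = ev$start, end = ev$end), 0, ch,
                   params)
  expect_true(st$tonic)
  re <- rescorePhasicInTonic(list(tr), 0, st$elevatedBaseline, params)
  expect_equal(nrow(re), 1)                # only the 3x burst survives
  expect_true(abs(re$start - 10) <= 0.045 && abs(re$end - 11) <= 0.045)
  # with no superimposed burst nothing survives rescoring
  flat <- EmgChannel("mentalis", rep(3 * b, fs * 30), fs)
  trF <- computeRmsTrack(flat, 0, 30, params)
  reF <- rescorePhasicInTonic(list(trF), 0, 3 * b, params)
  expect_equal(nrow(reF), 0)
})

test_that("mini-epoch scoring: phasic vs any vs tonic-epoch membership", {
  ep <- data.frame(start = 0, valid = TRUE, tonic = FALSE)
  # 1 s event inside mini-epoch 4 ([9, 12))
  mini <- scoreMiniEpochs(data.frame(start = 10, end = 11, duration = 1),
                          ep, params)
  expect_equal(which(mini$phasic), 4)
  expect_equal(which(mini$any), 4)
  # 7 s event spanning mini-epochs 2-4: intermediate, so any only
  mini <- scoreMiniEpochs(data.frame(start = 4, end = 11, duration = 7),
                          ep, params)
  expect_equal(which(mini$phasic), integer(0))
  expect_equal(which(mini$any), 2:4)
  # an event longer than 15 s in a non-tonic epoch counts nowhere
  mini <- scoreMiniEpochs(data.frame(start = 1, end = 17, duration = 16),
                          ep, params)
  expect_false(any(mini$phasic) || any(mini$any))
  # tonic epoch with no discrete events: all valid mini-epochs any
  epT <- data.frame(start = 0, valid = TRUE, tonic = TRUE)
  mini <- scoreMiniEpochs(emptyEv(), epT, params, tonicEvents = list())
  expect_true(all(mini$any))
  expect_false(any(mini$phasic))
  # invalid mini-epochs carry no flags
  mini <- scoreMiniEpochs(data.frame(start = 10, end = 11, duration = 1),
                          ep, params,
                          miniValid = c(rep(TRUE, 3), FALSE, rep(TRUE, 6)))
  expect_false(any(mini$phasic))
})

test_that("event categorization boundaries: 5 s phasic, 15 s intermediate", {
  ev <- categorizeEvents(data.frame(duration = c(0.105, 5.0, 5.01, 15.0,
                                                 15.015)), params)
  expect_equal(ev$category, c("phasic", "phasic", "intermediate",
                              "intermediate", "tonic"))
})
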