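# Baseline amplitude estimation, fallback and propagation.

params <- detectionParams()

test_that("stationary noise recovers its RMS as baseline", {
  set.seed(31)
  fs <- 256
  ch <- EmgChannel("mentalis", makeBandNoise(fs * 180, fs, 0.02), fs)
  est <- estimateBaseline(ch, data.frame(start = 0, end = 180), NULL,
                          params)
  expect_equal(est$source, "window30")
  expect_lt(abs(est$amplitude - 0.02), 0.002)       # within 10%
})

test_that("the minimum window comes from the quieter half", {
  set.seed(32)
  fs <- 256
  x <- c(makeBandNoise(fs * 90, fs, 0.05), makeBandNoise(fs * 90, fs, 0.02))
  est <- estimateBaseline(EmgChannel("mentalis", x, fs),
                          data.frame(start = 0, end = 180), NULL, params)
  expect_lt(est$amplitude, 0.03)
  # minimality: never above the literal RMS of any artefact-free window
  for (t in c(0, 40, 90, 120, 150)) {
    idx <- (round(t * fs) + 1):round((t + 30) * fs)
    expect_lte(est$amplitude, sqrt(mean(x[idx]^2)) + 1e-12)
  }
})

test_that("baselines scale with the signal", {
  set.seed(33)
  fs <- 256
  x <- makeBandNoise(fs * 180, fs, 0.05)
  seg <- data.frame(start = 0, end = 180)
  b1 <- estimateBaseline(EmgChannel("mentalis", x, fs), seg, NULL,
                         params)$amplitude
  b3 <- estimateBaseline(EmgChannel("mentalis", 3 * x, fs), seg, NULL,
                         params)$amplitude
  expect_equal(b3, 3 * b1, tolerance = 1e-12)
})

test_that("15 s fallback triggers exactly when no 30 s window fits", {
  set.seed(34)
  fs <- 256
  dur <- 160
  x <- makeBandNoise(fs * dur, fs, 0.1)
  ch <- EmgChannel("mentalis", x, fs)
  seg <- data.frame(start = 0, end = dur, isPeriod = TRUE)

  mkMask <- function(arousals) {
    buildArtefactMask(seg, list(do.call(EventList,
                                        c(list("arousal"), arousals))),
                      NULL, "mentalis", dur, params)
  }
  # central artefact leaves two 40 s clean runs: 30 s windows exist
  mask40 <- mkMask(list(start = 40, end = 120))
  est <- estimateBaseline(ch, seg, mask40, params)
  expect_equal(est$source, "window30")
  # artefacts leave only 20 s clean runs: the 15 s fallback must fire
  mask20 <- mkMask(list(start = c(20, 60, 100, 140),
                        end = c(40, 80, 120, 160)))
  est20 <- estimateBaseline(ch, seg, mask20, params)
  expect_equal(est20$source, "window15")
  # 10 s clean runs: nothing fits either window
  mask10 <- mkMask(list(start = seq(10, 150, by = 20),
                        end = pmin(seq(20, 160, by = 20), 160)))
  expect_equal(estimateBaseline(ch, seg, mask10, params)$source,
               "unavailable")

  # oracle: enumerate candidate windows on the grid, literal artefact check
  enumerateFits <- function(mask, w) {
    step <- params$rmsStep
    wc <- round(w / step)
    any(vapply(0:(round(dur / step) - wc), function(k)
      all(mask$valid[(k + 1):(k + wc)]), logical(1)))
  }
  expect_true(enumerateFits(mask40, 30))
  expect_false(enumerateFits(mask20, 30))
  expect_true(enumerateFits(mask20, 15))
  expect_false(enumerateFits(mask10, 15))
})

test_that("estimated minimum equals the literal window-enumeration minimum", {
  set.seed(35)
  fs <- 256
  dur <- 60
  x <- makeBandNoise(fs * dur, fs, 0.05)
  ch <- EmgChannel("mentalis", x, fs)
  est <- estimateBaseline(ch, data.frame(start = 0, end = dur), NULL,
                          params)
  step <- params$rmsStep
  starts <- seq(0, dur - 30, by = step)
  oracle <- min(vapply(starts, function(t) {
    idx <- which((seq_along(x) - 1) / fs >= t - 1e-12 &
                   (seq_along(x) - 1) / fs < t + 30 - 1e-12)
    sqrt(mean(x[idx]^2))
  }, numeric(1)))
  expect_equal(est$amplitude, oracle, tolerance = 1e-12)
})

test_that("baseline propagation: inheritance directions and bout tie-break", {
  segs <- data.frame(start = c(0, 300, 700, 1000),
                     end = c(180, 480, 880, 1030),
                     isPeriod = c(TRUE, TRUE, TRUE, FALSE))
  est <- function(a) if (is.na(a)) list(amplitude = NA_real_,
                                        source = "unavailable") else
    list(amplitude = a, source = "window30")

  # P2 unavailable inherits from previous P1
  b <- propagateBaseline(segs, list(est(0.02), est(NA), est(0.03),
                                    NULL), "mentalis")
  expect_equal(b$baseline[2], 0.02)
  expect_equal(b$source[2], "inherited_prev")

  # P1 unavailable inherits from the following measured period
  b <- propagateBaseline(segs, list(est(NA), est(0.03), est(0.04), NULL),
                         "mentalis")
  expect_equal(b$baseline[1], 0.03)
  expect_equal(b$source[1], "inherited_next")

  # transitive inheritance through consecutive unavailable periods
  b <- propagateBaseline(segs, list(est(0.02), est(NA), est(NA), NULL),
                         "mentalis")
  expect_equal(b$baseline[2:3], c(0.02, 0.02))

  # bout equidistant between two periods takes the earlier one
  segsTie <- data.frame(start = c(0, 210, 480), end = c(180, 240, 660),
                        isPeriod = c(TRUE, FALSE, TRUE))
  b <- propagateBaseline(segsTie, list(est(0.02), NULL, est(0.03)),
                         "mentalis")
  expect_equal(b$baseline[2], 0.02)
  expect_equal(b$source[2], "nearest_segment")

  # nearest-period assignment by midpoint distance
  segsNear <- data.frame(start = c(0, 400, 460), end = c(180, 430, 640),
                         isPeriod = c(TRUE, FALSE, TRUE))
  b <- propagateBaseline(segsNear, list(est(0.02), NULL, est(0.03)),
                         "mentalis")
  expect_equal(b$baseline[2], 0.03)
})

test_that("a channel with no measurable baseline raises a discard warning", {
  segs <- data.frame(start = 0, end = 180, isPeriod = TRUE)
  expect_warning(
    b <- propagateBaseline(segs, list(list(amplitude = NA_real_,
                                           source = "unavailable")),
                           "ta_left"),
    class = "rswaChannelDiscard")
  expect_equal(b$source, "unavailable")
})
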