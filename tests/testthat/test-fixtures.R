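# Synthetic fixture generator and the ground-truth verification harness.

test_that("identical seed and spec give identical fixtures", {
  spec <- fixtureSpec(seed = 51,
                      stages = data.frame(stage = c("W", "REM"),
                                          duration = c(30, 300)),
                      bursts = data.frame(channel = "mentalis", start = 60,
                                          duration = 2, ratio = 3))
  f1 <- generateFixture(spec, tempfile())
  f2 <- generateFixture(spec, tempfile())
  expect_identical(samples(f1$recording[["mentalis"]]),
                   samples(f2$recording[["mentalis"]]))
  expect_identical(f1$truth, f2$truth)
  expect_identical(unname(tools::md5sum(f1$paths[["edf"]])),
                   unname(tools::md5sum(f2$paths[["edf"]])))
  expect_identical(readLines(f1$paths[["hypnogram"]]),
                   readLines(f2$paths[["hypnogram"]]))
})

test_that("background RMS tracks the requested baseline within 5%", {
  fx <- generateFixture(fixtureSpec(seed = 52,
    stages = data.frame(stage = "REM", duration = 300),
    baselines = c(mentalis = 0.08)), tempfile())
  x <- samples(fx$recording[["mentalis"]])
  for (t0 in seq(0, 270, by = 30)) {
    idx <- (t0 * 256 + 1):((t0 + 30) * 256)
    expect_lt(abs(sqrt(mean(x[idx]^2)) - 0.08), 0.004)
  }
})

test_that("ground-truth categories follow the duration rules", {
  spec <- fixtureSpec(seed = 53,
    stages = data.frame(stage = "REM", duration = 600),
    bursts = data.frame(channel = "mentalis",
                        start = c(10, 60, 120, 210),
                        duration = c(2, 5, 8, 20), ratio = 3))
  fx <- generateFixture(spec, tempfile())
  expect_equal(fx$truth$category,
               c("phasic", "phasic", "intermediate", "tonic"))
})

test_that("bursts too close to merge are rejected unless marked", {
  stages <- data.frame(stage = "REM", duration = 300)
  bursts <- data.frame(channel = "mentalis", start = c(10, 12.1),
                       duration = c(2, 1), ratio = 3)
  expect_error(fixtureSpec(seed = 1, stages = stages, bursts = bursts),
               "merge")
  expect_s3_class(fixtureSpec(seed = 1, stages = stages, bursts = bursts,
                              allowMerge = TRUE), "FixtureSpec")
  outside <- data.frame(channel = "mentalis", start = 299, duration = 2,
                        ratio = 3)
  expect_error(fixtureSpec(seed = 1, stages = stages, bursts = outside),
               "inside the recording")
})

test_that("a burst-free fixture scores zero activity everywhere", {
  fx <- generateFixture(fixtureSpec(seed = 54,
    stages = data.frame(stage = c("N2", "REM", "N2", "REM"),
                        duration = c(60, 300, 60, 180))), tempfile())
  sc <- scoreRecording(fx$recording, fx$hypnogram, fx$events)
  s <- channelSummary(sc)
  expect_equal(s$nTonic + s$nPhasic + s$nAny, 0)
  expect_equal(nrow(rswaEvents(sc)), 0)
})

test_that("verification reports perfect recovery and detects misses", {
  spec <- fixtureSpec(seed = 55,
    stages = data.frame(stage = c("W", "REM"), duration = c(30, 600)),
    bursts = data.frame(channel = "mentalis",
                        start = c(40, 100, 160, 220),
                        duration = c(1, 2, 3, 8), ratio = 3.5))
  fx <- generateFixture(spec, tempfile())
  sc <- scoreRecording(fx$recording, fx$hypnogram, fx$events)
  v <- verifyAgainstTruth(sc, fx)
  pr <- v$mentalis$precisionRecall
  expect_equal(unname(pr$phasic["recall"]), 1)
  expect_equal(unname(pr$phasic["precision"]), 1)
  expect_equal(unname(pr$intermediate["recall"]), 1)
  expect_true(v$mentalis$withinTolerance)
  expect_equal(v$mentalis$counts$expected, v$mentalis$counts$observed)

  # an un-injected truth burst lowers recall to (K-1)/K
  fx2 <- fx
  fx2$truth <- rbind(fx2$truth,
                     data.frame(channel = "mentalis", start = 400,
                                duration = 1, ratio = 3.5, end = 401,
                                category = "phasic"))
  v2 <- verifyAgainstTruth(sc, fx2)
  expect_equal(unname(v2$mentalis$precisionRecall$phasic["recall"]), 3 / 4)
})

test_that("burst layout keeps margins and one burst per epoch", {
  h <- Hypnogram(seq(0, by = 30, length.out = 30), rep("REM", 30))
  b <- layoutBursts(h, "mentalis", nPhasic = 5, nIntermediate = 3,
                    nTonic = 2)
  expect_equal(nrow(b), 10)
  # each burst in its own epoch
  expect_equal(anyDuplicated(floor(b$start / 30)), 0)
  # margins to mini-epoch boundaries at least 0.25 s on both sides
  relS <- b$start %% 3
  relE <- (b$start + b$duration) %% 3
  expect_true(all(pmin(relS, 3 - relS) >= 0.25 |
                    abs(relS) < 1e-9))
  expect_true(all(pmin(relE, 3 - relE) >= 0.25))
  expect_true(all(relS >= 0.25))
  # categories by construction
  expect_equal(sum(b$duration <= 5), 5)
  expect_equal(sum(b$duration > 5 & b$duration <= 15), 3)
  expect_equal(sum(b$duration > 15), 2)
  expect_error(layoutBursts(h, "mentalis", nPhasic = 40), "not enough")
})
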