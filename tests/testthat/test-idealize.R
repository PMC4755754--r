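test_that("baseline estimation finds the dominant closed level", {
  expect_equal(estimateBaseline(numeric(100)), 0)
  ## leak offset with brief openings
  tr <- squarePulseTrace(c(0.1, 0.5), c(0.01, 0.02), -9, total_s = 1,
                         baseline_pA = -3.3)
  expect_equal(estimateBaseline(tr), -3.3, tolerance = 0.05)
  ## pure Gaussian noise: within 3 SE of the mean
  set.seed(1)
  x <- rnorm(20000, sd = 0.6)
  expect_lt(abs(estimateBaseline(x)), 3 * 0.6 / sqrt(20000) + 0.05)
})

test_that("ambiguous baselines warn and fall back to the median", {
  set.seed(2)
  x <- c(rnorm(5000, 0, 0.1), rnorm(5000, -9, 0.1), runif(20000, -20, 10))
  expect_warning(b <- estimateBaseline(x), "ambiguous")
  expect_equal(b, stats::median(x), tolerance = 1e-9)
})

test_that("noiseless flat traces produce no events", {
  tr <- squarePulseTrace(numeric(0), numeric(0), numeric(0), total_s = 0.5)
  rec <- detectEvents(tr, amplitude = 9)
  expect_identical(nrow(openDwells(rec)), 0L)
  expect_equal(computeNPo(rec), 0)
})

test_that("square pulses are recovered with exact durations", {
  durs <- c(0.6e-3, 0.8e-3, 2.0e-3)
  tr <- squarePulseTrace(c(0.1, 0.2, 0.3), durs, -9, total_s = 0.5)
  rec <- detectEvents(tr, amplitude = 9)
  op <- openDwells(rec)
  expect_identical(nrow(op), 3L)
  expect_equal(op$duration_s, durs, tolerance = 1 / 25000 / min(durs) + 0.01)
  expect_equal(op$mean_amplitude_pA, rep(-9, 3), tolerance = 0.01)
  expect_identical(op$level, rep(1L, 3))
})

test_that("sub-resolution crossings are rejected", {
  tr <- squarePulseTrace(0.1, 0.05e-3, -9, total_s = 0.2)
  rec <- detectEvents(tr, amplitude = 9, minDuration = 0.2)
  expect_identical(nrow(openDwells(rec)), 0L)
  expect_error(detectEvents(tr, amplitude = 9, minDuration = 0.01),
               "sampling interval")
  expect_error(detectEvents(tr, amplitude = 0), "amplitude")
})

test_that("stacked openings resolve at integer multiples of the amplitude", {
  ## overlapping pulses: level 1, then 2, then 1
  tr <- squarePulseTrace(c(0.1, 0.104), c(0.01, 0.002), -9, total_s = 0.2)
  rec <- detectEvents(tr, amplitude = 9)
  op <- openDwells(rec)
  expect_identical(max(op$level), 2L)
  expect_equal(computeNPo(rec), (0.01 + 0.002) / 0.2, tolerance = 0.02)
})

test_that("most ground-truth events of at least 0.4 ms are recovered", {
  rec <- makeScenario("cldn2_induced", seed = 7, duration = 30)
  det <- detectEvents(rec$trace, amplitude = 9)
  gt <- openDwells(rec$groundTruth$claudin2)
  dop <- openDwells(det)
  big <- gt[gt$duration_s >= 0.4e-3, ]
  hit <- vapply(seq_len(nrow(big)), function(i) {
    any(dop$start_s < big$start_s[i] + big$duration_s[i] &
        dop$start_s + dop$duration_s > big$start_s[i])
  }, logical(1))
  expect_gte(mean(hit), 0.9)
  ## no detected event where all channel classes are closed >= 5 ms around
  gtAll <- rbind(gt, openDwells(rec$groundTruth$independent))
  falsePos <- vapply(seq_len(nrow(dop)), function(i) {
    mid <- dop$start_s[i] + dop$duration_s[i] / 2
    !any(gtAll$start_s - 5e-3 < mid &
         gtAll$start_s + gtAll$duration_s + 5e-3 > mid)
  }, logical(1))
  expect_identical(sum(falsePos), 0L)
})

test_that("idealization is invariant to a constant offset", {
  rec <- makeScenario("cldn2_induced", seed = 13, duration = 5)
  tr <- rec$trace
  shifted <- new("CurrentTrace", current = currentSamples(tr) + 7.7,
                 samplingRate = samplingRate(tr), protocol = protocol(tr),
                 metadata = traceMetadata(tr))
  a <- detectEvents(tr, amplitude = 9)
  b <- detectEvents(shifted, amplitude = 9)
  expect_equal(dwells(a)$level, dwells(b)$level)
  expect_equal(dwells(a)$duration_s, dwells(b)$duration_s)
  expect_equal(baseline(b) - baseline(a), 7.7, tolerance = 0.02)
})

test_that("events split into large and small amplitude classes", {
  tr <- squarePulseTrace(c(0.1, 0.2), c(5e-3, 5e-3), c(-9, -4.3),
                         total_s = 0.5)
  rec <- detectEvents(tr, amplitude = 4.3)
  cls <- classifyEvents(rec, cut = 6)
  expect_identical(nrow(dwells(cls$large)), 1L)
  expect_identical(nrow(dwells(cls$small)), 1L)
  expect_equal(abs(dwells(cls$large)$mean_amplitude_pA), 9, tolerance = 0.05)
  ## empty record -> two empty classes
  empty <- detectEvents(squarePulseTrace(numeric(0), numeric(0), numeric(0),
                                         total_s = 0.2), amplitude = 9)
  cls0 <- classifyEvents(empty)
  expect_identical(nrow(dwells(cls0$large)), 0L)
  expect_identical(nrow(dwells(cls0$small)), 0L)
})

test_that("simulated mixed events classify with high agreement", {
  set.seed(5)
  n <- 100
  isLarge <- rep(c(TRUE, FALSE), length.out = n)
  starts <- seq(0.05, by = 0.02, length.out = n)
  amps <- ifelse(isLarge, -9, -4.3)
  tr <- squarePulseTrace(starts, rep(4e-3, n), amps, total_s = 2.1)
  ## mild noise on top
  tr@current <- tr@current + rnorm(length(tr@current), sd = 0.3)
  rec <- detectEvents(tr, amplitude = 4.3)
  op <- openDwells(rec)
  expect_gte(nrow(op), 0.95 * n)
  predLarge <- abs(op$mean_amplitude_pA) >= 6
  trueLarge <- isLarge[findInterval(op$start_s + op$duration_s / 2, starts)]
  expect_gte(mean(predLarge == trueLarge), 0.98)
})

test_that("NPo matches the quoted sum and hand oracles", {
  mk <- function(levels, durs, tot) {
    starts <- cumsum(c(0, head(durs, -1)))
    new("IdealizedRecord",
        dwells = data.frame(level = as.integer(levels), start_s = starts,
                            duration_s = durs,
                            mean_amplitude_pA = ifelse(levels > 0, -9, NA)),
        totalTime = tot, baseline = 0)
  }
  expect_equal(computeNPo(mk(1, 1, 10)), 0.1)
  ## level-1 for 2 s and level-2 for 1 s in 10 s: (2*1 + 1*2)/10
  expect_equal(computeNPo(mk(c(1, 0, 2), c(2, 3, 1), 10)), 0.4)
})

test_that("NPo equals a brute-force per-sample oracle on noiseless traces", {
  set.seed(31)
  m <- claudin2Model()
  p <- simulateStatePath(m, 60)
  ## unfiltered, noise-free rendering for the exact oracle
  cfg <- recordingConfig(samplingRate = 50000, filterCutoff = 50,
                         noiseSD = 0, sealResistance = Inf, duration = 60)
  n <- round(60 * 50000)
  t <- (seq_len(n) - 0.5) / 50000
  g <- poreConductance(m)[match(p$state, stateLabels(m))]
  idx <- findInterval(t, p$start_s)
  x <- g[pmax(idx, 1)] * -100 / 1000
  tr <- new("CurrentTrace", current = x, samplingRate = 50000,
            protocol = holdProtocol(-100, 60), metadata = list())
  ## single-sample dead time so no sub-resolution merging occurs
  rec <- detectEvents(tr, amplitude = 9, baseline = 0,
                      minDuration = 1000 / 50000)
  expect_equal(computeNPo(rec), bruteForceNPo(tr, 9), tolerance = 1e-9)
})

test_that("NPo of k identical channels is about k times one channel", {
  m <- twoStateModel(tauOpen = 2e-3, tauClosed = 18e-3)
  set.seed(77)
  one <- replicate(6, {
    p <- simulateStatePath(m, 50)
    sum(p$duration_s[p$class == "open"]) / 50
  })
  three <- replicate(6, {
    ps <- replicate(3, simulateStatePath(m, 50), simplify = FALSE)
    sum(vapply(ps, function(p)
      sum(p$duration_s[p$class == "open"]), numeric(1))) / 50
  })
  expect_equal(mean(three) / mean(one), 3, tolerance = 0.2)
})

test_that("NPo reduction arithmetic", {
  expect_equal(npoReduction(0.4, 0.05), 87.5)
  expect_equal(npoReduction(0.2, 0.2), 0)
  expect_equal(npoReduction(0.2, 0), 100)
  expect_error(npoReduction(0, 0.1), "> 0")
})
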