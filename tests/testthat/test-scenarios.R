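test_that("unknown scenario names are rejected", {
  expect_error(makeScenario("no_such_condition", seed = 1), "arg")
})

test_that("parental recordings contain no claudin-2-class events", {
  rec <- makeScenario("parental", seed = 21, duration = 10)
  expect_false("claudin2" %in% names(rec$groundTruth))
  expect_true("independent" %in% names(rec$groundTruth))
})

test_that("lanthanum block drives claudin-2 NPo to zero after onset", {
  rec <- makeScenario("la3_block", seed = 9, duration = 30)
  onset <- rec$scenario@blockOnset
  d <- dwells(rec$groundTruth$claudin2)
  after <- d[d$start_s >= onset & d$level > 0, ]
  expect_identical(nrow(after), 0L)
  ## and the idealizer agrees on the post-onset segment
  det <- detectEvents(rec$trace, amplitude = 9)
  op <- openDwells(det)
  op <- op[op$start_s > onset + 0.5 & abs(op$mean_amplitude_pA) >= 6, ]
  expect_identical(nrow(op), 0L)
})

test_that("MTSET block decays the active claudin-2 channel count", {
  ## events persist briefly after onset but disappear within ~20 s
  counts <- vapply(1:6, function(s) {
    rec <- makeScenario("mtset_i66c", seed = 100 + s, duration = 40)
    d <- openDwells(rec$groundTruth$claudin2)
    onset <- rec$scenario@blockOnset
    c(before = sum(d$start_s < onset),
      late = sum(d$start_s > onset + 25))
  }, numeric(2))
  expect_gt(sum(counts["before", ]), 0)
  expect_lt(sum(counts["late", ]), 0.1 * sum(counts["before", ]) + 2)
})

test_that("off-junction recordings show only small events, more at +100 mV", {
  pos <- 0; neg <- 0; amps <- numeric(0)
  for (s in 31:33) {
    rec <- makeScenario("off_junction", seed = s, duration = 20)
    gt <- openDwells(rec$groundTruth$membrane)
    half <- protocolDuration(rec$scenario@protocol) / 2
    neg <- neg + sum(gt$start_s < half)
    pos <- pos + sum(gt$start_s >= half)
    amps <- c(amps, abs(gt$mean_amplitude_pA))
  }
  expect_true(all(amps < 2))
  expect_gt(pos, neg)
})

test_that("off-junction events need 500 Hz filtering to resolve", {
  rec <- makeScenario("off_junction", seed = 4, duration = 20)
  halves <- splitBySegments(refilterTrace(rec$trace, 500))
  found <- vapply(halves, function(h) {
    nrow(openDwells(detectEvents(h, amplitude = 1.5, minDuration = 1)))
  }, numeric(1))
  expect_gt(sum(found), 0)
  ## all detected amplitudes stay below 2 pA
  for (h in halves) {
    op <- openDwells(detectEvents(h, amplitude = 1.5, minDuration = 1))
    if (nrow(op)) expect_true(all(abs(op$mean_amplitude_pA) < 2))
  }
})

test_that("suppression reduces expected claudin-2 NPo about 8-fold", {
  ## expression-proportional insertion: suppressed slots active w.p. 1/8,
  ## so the expected active-channel count (hence NPo) ratio is 0.125
  sc <- scenarioDefinition("cldn2_suppressed")
  cc <- sc@channelClasses[[1]]
  expect_identical(cc$class, "claudin2")
  expect_equal(cc$n * cc$p_active / 3, 1 / 8)
  nActive <- vapply(1:400, function(s) {
    set.seed(s); stats::rbinom(1, cc$n, cc$p_active)
  }, numeric(1))
  expect_equal(mean(nActive), 3 / 8, tolerance = 0.2)
})

test_that("cooling scales gating rates and expected channel count by 0.63", {
  sc <- scenarioDefinition("cooled")
  expect_equal(sc@config@temperatureScale, 0.63)
  cc <- sc@channelClasses[[1]]
  expect_equal(cc$p_active, 0.63)
  warm <- claudin2Model()
  expect_equal(transitionRates(cc$model), 0.63 * transitionRates(warm))
  ## cold-resistant independent class untouched
  indep <- sc@channelClasses[[2]]
  expect_equal(transitionRates(indep$model),
               transitionRates(independentChannelModel()))
})

test_that("scenario generation is reproducible for a fixed seed", {
  a <- makeScenario("cldn2_induced", seed = 17, duration = 5)
  b <- makeScenario("cldn2_induced", seed = 17, duration = 5)
  expect_identical(currentSamples(a$trace), currentSamples(b$trace))
  expect_identical(dwells(a$groundTruth$claudin2),
                   dwells(b$groundTruth$claudin2))
})

test_that("scenario ground truth matches rendered amplitudes", {
  rec <- makeScenario("cldn2_induced", seed = 2, duration = 10)
  gt <- openDwells(rec$groundTruth$claudin2)
  lev1 <- gt[gt$level == 1L, ]
  expect_true(all(abs(lev1$mean_amplitude_pA + 9) < 1e-9))
})
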