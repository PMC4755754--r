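test_that("all-points histogram mass is normalized to record duration", {
  rec <- makeScenario("parental", seed = 3, duration = 5)
  h <- allPointsHistogram(rec$trace)
  expect_equal(diff(h@breaks[1:2]), 0.1)
  ## total sample count over the sampling rate recovers the duration
  expect_equal(sum(h@counts) / samplingRate(h), 5, tolerance = 1e-9)
  ## density is counts per second of record
  expect_equal(sum(h@density), sum(h@counts) / 5, tolerance = 1e-9)
  expect_equal(sum(h@counts), length(currentSamples(rec$trace)))
})

test_that("constant and two-level traces occupy the expected bins", {
  tr0 <- squarePulseTrace(numeric(0), numeric(0), numeric(0), total_s = 0.1)
  h0 <- allPointsHistogram(tr0)
  expect_identical(sum(h0@counts > 0), 1L)
  mids <- (h0@breaks[-1] + h0@breaks[-length(h0@breaks)]) / 2
  expect_lt(abs(mids[which(h0@counts > 0)]), 0.1)

  ## 70/30 split between 0 and -9 pA
  tr <- squarePulseTrace(0, 0.3, -9, total_s = 1)
  h <- allPointsHistogram(tr)
  occ <- which(h@counts > 0)
  expect_identical(length(occ), 2L)
  expect_equal(sort(h@counts[occ] / sum(h@counts)), c(0.3, 0.7),
               tolerance = 1e-3)
})

test_that("Gaussian mixture recovers three amplitude populations", {
  set.seed(12)
  n <- 1e6
  comp <- sample(1:3, n, replace = TRUE, prob = c(0.7, 0.15, 0.15))
  x <- rnorm(n, mean = c(0, -4.3, -9)[comp], sd = 0.45)
  tr <- new("CurrentTrace", current = x, samplingRate = 25000,
            protocol = holdProtocol(-100, n / 25000), metadata = list())
  h <- fitGaussianMixture(allPointsHistogram(tr), k = 3)
  cmp <- componentTable(h)
  expect_equal(cmp$mean, c(-9, -4.3, 0), tolerance = 0.1 / 4.3)
  expect_equal(sum(cmp$weight), 1)
  ## independent oracle: mclust EM on a subsample of the raw (unbinned)
  ## samples, started from a coarse amplitude partition
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  sub <- x[seq(1, n, by = 50)]
  grp <- cut(sub, c(-Inf, -6.5, -2, Inf))
  init <- list(
    pro = as.numeric(table(grp)) / length(sub),
    mean = as.numeric(tapply(sub, grp, mean)),
    variance = list(modelName = "V", d = 1, G = 3,
                    sigmasq = as.numeric(tapply(sub, grp, stats::var))))
  mc <- em(modelName = "V", data = sub, parameters = init)
  expect_equal(sort(as.numeric(mc$parameters$mean)), sort(cmp$mean),
               tolerance = 0.05)
})

test_that("single-component Gaussian fit matches the sample mean", {
  set.seed(4)
  x <- rnorm(2e5, mean = -3.3, sd = 0.6)
  tr <- new("CurrentTrace", current = x, samplingRate = 25000,
            protocol = holdProtocol(-100, 8), metadata = list())
  h <- fitGaussianMixture(allPointsHistogram(tr), k = 1)
  expect_equal(componentTable(h)$mean, mean(x), tolerance = 0.01)
})

test_that("degenerate all-equal data hit the sd floor and are flagged", {
  x <- rep(0.05, 1000)
  tr <- new("CurrentTrace", current = x, samplingRate = 1000,
            protocol = holdProtocol(-100, 1), metadata = list())
  fit <- fitGaussianMixture(allPointsHistogram(tr), k = 1)
  cmp <- componentTable(fit)
  expect_true(attr(cmp, "sdFloored"))
  expect_equal(cmp$sd, 0.1)            # bin-width floor
  expect_lt(abs(cmp$mean - 0.05), 0.1) # within the occupied bin
})

test_that("mixture fit needs enough occupied bins", {
  tr <- squarePulseTrace(0, 0.3, -9, total_s = 1)
  expect_error(fitGaussianMixture(allPointsHistogram(tr), k = 3),
               "occupied bins")
})

test_that("log-binned dwell histograms conserve counts", {
  d <- c(0.001, 0.01, 0.1)
  h <- dwellHistogram(d)
  expect_equal(sum(h$count), 3)
  expect_identical(sum(h$count > 0), 3L)  # three distinct decades
  expect_error(dwellHistogram(c(1, -1)), "> 0")

  set.seed(9)
  d2 <- rexp(10000, 1 / 0.6e-3)
  h2 <- dwellHistogram(d2)
  expect_equal(sum(h2$count), 10000)
  peak <- h2[which.max(h2$count), ]
  expect_true(peak$lower_s < 0.6e-3 && peak$upper_s > 0.2e-3)
})

test_that("single-exponential ML estimate equals the sample mean exactly", {
  set.seed(2)
  d <- rexp(500, 1 / 0.6e-3)
  fit <- fitDwellExponentials(d, nComponents = 1, stateClass = "open")
  expect_identical(timeConstants(fit), mean(d))
  expect_equal(fit@logLik, sum(dexp(d, 1 / mean(d), log = TRUE)))
})

test_that("two-component mixtures are recovered within 15 percent", {
  set.seed(6)
  n <- 5000
  fast <- rexp(round(0.9 * n), 1 / 1.2e-3)
  slow <- rexp(n - round(0.9 * n), 1 / 3)
  fit <- fitDwellExponentials(c(fast, slow), nComponents = 2,
                              stateClass = "closed")
  taus <- timeConstants(fit)
  expect_equal(taus[1], 1.2e-3, tolerance = 0.15)
  expect_equal(taus[2], 3, tolerance = 0.15)
  expect_equal(componentTable(fit)$fraction[1], 0.9, tolerance = 0.05)
  expect_lt(fit@lrtP, 1e-6)
})

test_that("median tau error over 20 replicates stays below 10 percent", {
  set.seed(2024)
  errs <- t(replicate(20, {
    d <- c(rexp(4500, 1 / 1.2e-3), rexp(500, 1 / 3))
    taus <- timeConstants(fitDwellExponentials(d, nComponents = 2))
    abs(taus - c(1.2e-3, 3)) / c(1.2e-3, 3)
  }))
  expect_lte(stats::median(errs[, 1]), 0.10)
  expect_lte(stats::median(errs[, 2]), 0.10)
})

test_that("model selection distinguishes one from two closed states", {
  set.seed(8)
  ## genuine mixture -> two components
  two <- fitDwellExponentials(c(rexp(2000, 1 / 1.2e-3), rexp(400, 1 / 3)),
                              stateClass = "closed")
  ## pure exponential -> one component
  one <- fitDwellExponentials(rexp(2000, 1 / 5e-3), stateClass = "closed")
  expect_identical(nrow(componentTable(two)), 2L)
  expect_identical(nrow(componentTable(one)), 1L)

  openFit <- fitDwellExponentials(rexp(1500, 1 / 0.6e-3), stateClass = "open")
  ks <- classifyKineticStates(openFit, two)
  expect_identical(ks$nOpen, 1L)
  expect_identical(ks$nClosed, 2L)
  expect_identical(ks$closedComponents$state, c("c_transient", "c_stable"))
  ks1 <- classifyKineticStates(openFit, one)
  expect_identical(ks1$nClosed, 1L)
})

test_that("a vanishing fraction collapses to one closed state", {
  fit <- new("DwellTimeFit", stateClass = "closed",
             components = data.frame(tau_s = c(1e-3, 2), fraction = c(1, 0)),
             nEvents = 100, logLik = 0, lrtP = NA_real_)
  openFit <- new("DwellTimeFit", stateClass = "open",
                 components = data.frame(tau_s = 6e-4, fraction = 1),
                 nEvents = 100, logLik = 0, lrtP = NA_real_)
  expect_identical(classifyKineticStates(openFit, fit)$nClosed, 1L)
})

test_that("insufficient events are refused", {
  expect_error(fitDwellExponentials(rexp(5, 1), nComponents = 1), "insufficient")
  expect_error(fitDwellExponentials(rexp(20, 1), nComponents = 2), "insufficient")
  expect_error(fitDwellExponentials(c(-1, 1), nComponents = 1), "> 0")
})
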