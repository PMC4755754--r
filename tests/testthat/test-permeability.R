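test_that("TER follows Ohm's law with area scaling", {
  expect_equal(terFromPulses(1, 10, 0.33), 33)
  expect_equal(terFromPulses(1, 10, 0.66), 66)  # doubling area doubles TER
  expect_equal(terFromPulses(0, 5, 0.33), 0)
  expect_error(terFromPulses(1, 0, 0.33), "zero")
})

test_that("GHK reversal is zero for symmetric compartments", {
  for (p in c(0.1, 1, 7.4, 9.5, 100))
    expect_equal(ghkVrev(naclConditions(), p), 0)
  ## symmetric-salt cancellation: dilution with p_ratio 1
  expect_equal(ghkVrev(naclConditions(13.5, 135), 1), 0, tolerance = 1e-12)
})

test_that("GHK approaches the Nernst limit as chloride permeability vanishes", {
  cond <- naclConditions(13.5, 135)
  aHi <- 135 * 0.755; aLo <- 13.5 * 0.882
  nernst <- thermalVoltage(310.15) * log(aHi / aLo)
  expect_equal(nernst, 57.4, tolerance = 0.001)
  expect_equal(ghkVrev(cond, 1e12), nernst, tolerance = 1e-6)
})

test_that("GHK is antisymmetric and monotone in the permeability ratio", {
  a <- naclConditions(13.5, 135)
  b <- naclConditions(135, 13.5)
  for (p in c(0.5, 2, 9.5))
    expect_equal(ghkVrev(a, p), -ghkVrev(b, p), tolerance = 1e-12)
  v <- vapply(c(0.1, 0.5, 1, 2, 9.5, 50), function(p) ghkVrev(a, p),
              numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("GHK inversion round-trips to 1e-6 over two decades", {
  cond <- naclConditions(13.5, 135)
  for (p in c(0.1, 0.5, 1, 2, 9.5, 30, 100)) {
    v <- ghkVrev(cond, p)
    expect_equal(invertGhkDilution(v, cond), p, tolerance = 1e-6)
  }
  expect_equal(invertGhkDilution(0, cond), 1, tolerance = 1e-9)
  ## outside the Nernst bounds there is no solution
  expect_error(invertGhkDilution(70, cond), "Nernst")
  ## just inside the bound: very large but finite
  vMax <- ghkVrev(cond, 1e8)
  expect_gt(invertGhkDilution(vMax - 0.01, cond), 1000)
})

test_that("biionic substitution recovers relative cation permeabilities", {
  cond <- biionicConditions("MA")
  ## identical cation behaves like Na: Vrev 0 implies ratio 1
  expect_equal(biionicPxOverPna(0, cond, pNaPCl = 9.5), 1, tolerance = 1e-9)
  ## forward-model round trip at low permeability (large cation)
  for (r in c(0.1, 0.3, 1, 2)) {
    v <- ghkVrev(cond, 9.5, pXPNa = r)
    expect_equal(biionicPxOverPna(v, cond, 9.5), r, tolerance = 1e-9)
  }
  ## methylamine-like near-zero shift means near-Na conductance
  vSmall <- ghkVrev(cond, 9.5, pXPNa = 0.97)
  expect_lt(abs(vSmall), 1)
})

test_that("Kimizuka-Koketsu permeability matches a hand computation", {
  ## independent arithmetic: (RT/F^2) * G * p/(1+p) / aNa
  R <- 8.31446261815324; T <- 310.15; F <- 96485.33212
  aNa <- 0.755 * 135 * 1e-6            # mol/cm^3
  byHand <- (R * T / F^2) * (1 / 100) * (9.5 / 10.5) / aNa
  expect_equal(kimizukaKoketsuPNa(100, 9.5, naclConditions()), byHand,
               tolerance = 1e-12)
  ## linear in conductance: halving TER doubles permeability
  expect_equal(kimizukaKoketsuPNa(50, 9.5), 2 * kimizukaKoketsuPNa(100, 9.5))
  ## p -> Inf limit
  expect_equal(kimizukaKoketsuPNa(100, 1e12),
               (R * T / F^2) * (1 / 100) / aNa, tolerance = 1e-9)
  expect_error(kimizukaKoketsuPNa(0, 9.5), "TER")
})

test_that("activity coefficients interpolate between the bench anchors", {
  expect_equal(naclActivityCoefficient(c(13.5, 67.5, 135)),
               c(0.882, 0.812, 0.755))
  mid <- naclActivityCoefficient(30)
  expect_true(mid < 0.882 && mid > 0.812)
  expect_equal(naclActivityCoefficient(500), 0.755)  # clamped
})

test_that("ohmic pathway algebra reproduces the worked resistances", {
  expect_equal(ohmicResistance(9, 100, digits = 2), 11)
  expect_equal(ohmicResistance(4, 100), 25)
  expect_equal(ohmicResistance(2, 100), 50)
  expect_equal(ohmicResistance(3.5, 100), 100 / 3.5)
  expect_equal(ohmicResistance(3.5, 100, digits = 1), 30)
  expect_equal(pathwayCurrent(25, 100), 4)
  expect_error(ohmicResistance(0, 100), "zero")
  expect_error(pathwayCurrent(0, 100), "zero")
  ## V = I R round trip is exact
  for (r in c(11, 25, 50))
    expect_equal(ohmicResistance(pathwayCurrent(r, 100), 100), r)
})

test_that("areal resistance converts to absolute resistance", {
  expect_equal(arealToAbsolute(1500, 0.33), 0.0045, tolerance = 0.02)
  expect_equal(arealToAbsolute(100, 0.33), 0.0003, tolerance = 0.02)
  expect_equal(arealToAbsolute(7, 1), 7e-6)   # x Ohm exactly, in MOhm
  expect_error(arealToAbsolute(100, 0), "> 0")
})

test_that("circuit pathways combine in series and parallel", {
  cm <- circuitModel()
  ## electrode (2.5 MOhm) in series with the 11 GOhm channel
  expect_equal(combinePathways(cm, "series",
                               c("electrode", "cldn2_channel")), 11.0025)
  expect_equal(combinePathways(cm, "parallel",
                               c("seal_leak", "seal_leak")), 15)
  par <- combinePathways(cm, "parallel",
                         c("cldn2_channel", "independent_channel", "seal_leak"))
  expect_lt(par, 11)  # parallel result below the smallest branch
  expect_error(combinePathways(cm, "series", character(0)), "non-empty")
  expect_error(combinePathways(cm, "series", "nonexistent"), "unknown")
})

test_that("Holm adjustment is monotone and never below raw p-values", {
  expect_equal(holmBonferroni(0.03), 0.03)
  expect_equal(holmBonferroni(c(0.01, 0.04)), c(0.02, 0.04))
  set.seed(14)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    adj <- holmBonferroni(p)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    expect_true(all(adj <= 1))
  }
  expect_error(holmBonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("t-test helper handles equal and distinct groups", {
  r <- twoSampleT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  set.seed(5)
  r2 <- twoSampleT(rnorm(30), rnorm(30, 5))
  expect_lt(r2$p, 1e-6)
  expect_error(twoSampleT(1, c(1, 2)), "at least 2")
})
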