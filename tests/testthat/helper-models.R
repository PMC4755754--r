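# Shared helpers: tiny models, noiseless configurations and synthetic traces
# built in code.

# Two-state model with given mean open/closed dwells.
twoStateModel <- function(tauOpen = 1e-3, tauClosed = 10e-3,
                          conductance = 90) {
  gatingModel(c("c", "o"), c("closed", "open"),
              rates = matrix(c(0, 1 / tauClosed,
                               1 / tauOpen, 0), 2, 2, byrow = TRUE),
              poreConductance = c(0, conductance))
}

# "Frozen" model: effectively no transitions, used to pin a channel open.
frozenModel <- function(conductance = 90, reversalPotential = 0) {
  gatingModel(c("c", "o"), c("closed", "open"),
              rates = matrix(0, 2, 2),
              poreConductance = c(0, conductance),
              reversalPotential = reversalPotential)
}

noiselessConfig <- function(duration, samplingRate = 25000,
                            sealResistance = Inf) {
  recordingConfig(samplingRate = samplingRate, filterCutoff = 5000,
                  noiseSD = 0, sealResistance = sealResistance,
                  duration = duration)
}

# Noise-free square-pulse trace: openings of given amplitude (pA, signed)
# and durations (s) at given start times, on a flat baseline.
squarePulseTrace <- function(starts_s, durations_s, amplitude_pA,
                             total_s, baseline_pA = 0,
                             samplingRate = 25000, voltage_mV = -100) {
  n <- round(total_s * samplingRate)
  x <- rep(baseline_pA, n)
  t <- (seq_len(n) - 0.5) / samplingRate
  for (i in seq_along(starts_s)) {
    sel <- t >= starts_s[i] & t < starts_s[i] + durations_s[i]
    x[sel] <- x[sel] + amplitude_pA[min(i, length(amplitude_pA))]
  }
  new("CurrentTrace", current = x, samplingRate = samplingRate,
      protocol = holdProtocol(voltage_mV, total_s), metadata = list())
}

# Brute-force NPo oracle: per-sample open-channel count above half
# amplitude, averaged over the record.
bruteForceNPo <- function(trace, amplitude, baseline = 0, direction = -1) {
  x <- (currentSamples(trace) - baseline) * direction
  mean(pmax(0, floor(x / amplitude + 0.5)))
}
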