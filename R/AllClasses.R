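#' @import methods
NULL

## ---------------------------------------------------------------------------
## GatingModel: labelled-state continuous-time Markov generator plus per-state
## conductance. The default model has one open state flanked by a transient
## and a stable closed state (c_stable <-> o <-> c_transient), so openings
## cluster into bursts terminated by entry into the stable closure.
## ---------------------------------------------------------------------------

#' Continuous-time Markov gating model for a single channel
#'
#' A \code{GatingModel} holds the labelled-state rate generator (Q matrix) of
#' a single channel together with the pore conductance of each state and the
#' channel reversal potential. Off-diagonal entries of \code{rates} are
#' transition rates in 1/s; each diagonal entry is the negative row sum so
#' rows sum to zero. Closed states must have zero conductance.
#'
#' @slot stateLabels Character vector of state names.
#' @slot stateClass Character vector, one of \code{"open"}/\code{"closed"}
#'   per state.
#' @slot rates Square numeric matrix of transition rates (1/s).
#' @slot poreConductance Numeric vector, conductance in pS per state
#'   (0 for closed states).
#' @slot reversalPotential Numeric scalar, channel reversal potential in mV.
#'
#' @seealso [gatingModel()], [claudin2Model()], [simulateStatePath()]
#' @export
setClass("GatingModel",
  representation(
    stateLabels = "character",
    stateClass = "character",
    rates = "matrix",
    poreConductance = "numeric",
    reversalPotential = "numeric"
  )
)

setValidity("GatingModel", function(object) {
  n <- length(object@stateLabels)
  msg <- character()
  if (n < 1L) msg <- c(msg, "at least one state required")
  if (length(object@stateClass) != n ||
      !all(object@stateClass %in% c("open", "closed")))
    msg <- c(msg, "stateClass must be 'open'/'closed', one per state")
  if (!all(dim(object@rates) == c(n, n)))
    msg <- c(msg, "rates must be a square matrix matching stateLabels")
  else {
    off <- object@rates
    diag(off) <- 0
    if (any(off < 0)) msg <- c(msg, "off-diagonal rates must be >= 0")
    if (any(abs(rowSums(object@rates)) > 1e-8 * (1 + abs(diag(object@rates)))))
      msg <- c(msg, "rate-matrix rows must sum to 0 (generator)")
  }
  if (!any(object@stateClass == "open") || !any(object@stateClass == "closed"))
    msg <- c(msg, "need at least one open and one closed state")
  if (length(object@poreConductance) != n || any(object@poreConductance < 0))
    msg <- c(msg, "poreConductance must be >= 0 per state")
  if (any(object@poreConductance[object@stateClass == "closed"] != 0))
    msg <- c(msg, "closed states must have zero conductance")
  if (length(object@reversalPotential) != 1L ||
      !is.finite(object@reversalPotential))
    msg <- c(msg, "reversalPotential must be a finite scalar (mV)")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## VoltageProtocol: piecewise hold/ramp command voltage.
## ---------------------------------------------------------------------------

#' Command-voltage protocol
#'
#' Ordered hold and ramp segments. Ramp segments interpolate linearly from
#' \code{start_mV} to \code{end_mV} over \code{duration_s}.
#'
#' @slot segments data.frame with columns \code{kind} ("hold" or "ramp"),
#'   \code{start_mV}, \code{end_mV}, \code{duration_s}.
#' @seealso [holdProtocol()], [rampProtocol()], [protocolVoltage()]
#' @export
setClass("VoltageProtocol", representation(segments = "data.frame"))

setValidity("VoltageProtocol", function(object) {
  s <- object@segments
  need <- c("kind", "start_mV", "end_mV", "duration_s")
  if (!all(need %in% names(s))) return("segments needs kind/start_mV/end_mV/duration_s")
  if (nrow(s) < 1L || sum(s$duration_s) <= 0) return("total duration must be > 0")
  if (!all(s$kind %in% c("hold", "ramp"))) return("kind must be 'hold' or 'ramp'")
  if (any(s$duration_s <= 0)) return("segment durations must be > 0")
  if (any(s$kind == "hold" & s$start_mV != s$end_mV))
    return("hold segments must have start_mV == end_mV")
  TRUE
})

## ---------------------------------------------------------------------------
## RecordingConfig: emulated recording-system parameters.
## ---------------------------------------------------------------------------

#' Recording-system configuration
#'
#' Parameters of the emulated patch-clamp recording: sampling rate, low-pass
#' filter cutoff (4-pole Bessel), baseline noise, seal-leak resistance, record
#' duration and a phenomenological temperature scale that multiplies all
#' gating rates and the expected active-channel count.
#'
#' @slot samplingRate Sampling rate, Hz.
#' @slot filterCutoff Low-pass cutoff, Hz (must be <= samplingRate/2).
#' @slot noiseSD Baseline Gaussian noise SD, pA, at the output rate.
#' @slot sealResistance Seal-leak resistance, GOhm (\code{Inf} = no leak).
#' @slot duration Record duration, s.
#' @slot temperatureScale Dimensionless multiplier on rates and channel count.
#' @seealso [recordingConfig()]
#' @export
setClass("RecordingConfig",
  representation(
    samplingRate = "numeric",
    filterCutoff = "numeric",
    noiseSD = "numeric",
    sealResistance = "numeric",
    duration = "numeric",
    temperatureScale = "numeric"
  )
)

setValidity("RecordingConfig", function(object) {
  msg <- character()
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be > 0")
  if (object@filterCutoff > object@samplingRate / 2)
    msg <- c(msg, "samplingRate must be >= 2 * filterCutoff")
  if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
  if (object@sealResistance <= 0) msg <- c(msg, "sealResistance must be > 0")
  if (object@duration <= 0) msg <- c(msg, "duration must be > 0")
  if (object@temperatureScale <= 0) msg <- c(msg, "temperatureScale must be > 0")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## CurrentTrace: sampled current with its protocol and provenance metadata.
## ---------------------------------------------------------------------------

#' Sampled current trace
#'
#' Current samples in pA at a fixed sampling rate, together with the command
#' voltage protocol and free-form metadata (scenario name, seed, provenance).
#' Negative current corresponds to cations moving towards the recording
#' (apical) electrode.
#'
#' @slot current Numeric vector, pA.
#' @slot samplingRate Hz.
#' @slot protocol A [VoltageProtocol-class].
#' @slot metadata Named list.
#' @export
setClass("CurrentTrace",
  representation(
    current = "numeric",
    samplingRate = "numeric",
    protocol = "VoltageProtocol",
    metadata = "list"
  )
)

setValidity("CurrentTrace", function(object) {
  if (object@samplingRate <= 0) return("samplingRate must be > 0")
  if (length(object@current) && !all(is.finite(object@current)))
    return("current samples must be finite")
  TRUE
})

## ---------------------------------------------------------------------------
## IdealizedRecord: ordered dwell table (level, start, duration, amplitude).
## ---------------------------------------------------------------------------

#' Idealized dwell record
#'
#' Ordered, non-overlapping dwell table produced by idealization (or carried
#' as simulation ground truth). \code{level} is the integer number of
#' simultaneously open channels (0 = all closed); \code{mean_amplitude_pA} is
#' the baseline-subtracted mean current during the dwell (NA for level 0).
#'
#' @slot dwells data.frame with columns \code{level}, \code{start_s},
#'   \code{duration_s}, \code{mean_amplitude_pA} and optionally \code{class}.
#' @slot totalTime Record length, s.
#' @slot baseline Baseline (closed-level) current, pA.
#' @seealso [detectEvents()], [computeNPo()], [openDwells()]
#' @export
setClass("IdealizedRecord",
  representation(
    dwells = "data.frame",
    totalTime = "numeric",
    baseline = "numeric"
  )
)

setValidity("IdealizedRecord", function(object) {
  d <- object@dwells
  need <- c("level", "start_s", "duration_s", "mean_amplitude_pA")
  if (!all(need %in% names(d)))
    return("dwells needs level/start_s/duration_s/mean_amplitude_pA")
  if (object@totalTime <= 0) return("totalTime must be > 0")
  if (nrow(d)) {
    if (any(d$duration_s <= 0)) return("dwell durations must be > 0")
    if (any(d$level < 0)) return("levels must be >= 0")
    if (is.unsorted(d$start_s)) return("dwells must be ordered by start")
    if (nrow(d) > 1L &&
        any(d$start_s[-1L] - (d$start_s + d$duration_s)[-nrow(d)] < -1e-9))
      return("dwells must not overlap")
    if (sum(d$duration_s) > object@totalTime * (1 + 1e-9))
      return("sum of dwell durations must be <= totalTime")
  }
  TRUE
})

## ---------------------------------------------------------------------------
## Scenario: named experimental condition = channel classes + protocol +
## recording config + optional block dynamics.
## ---------------------------------------------------------------------------

#' Experimental scenario
#'
#' A named experimental condition: one or more channel classes (each a
#' [GatingModel-class] with a channel count or a per-slot expression
#' probability), a voltage protocol, a recording configuration and optional
#' block dynamics (e.g. lanthanum or MTSET block of the claudin-2 class).
#'
#' @slot name Scenario name.
#' @slot channelClasses List; each element a list with fields \code{model}
#'   (GatingModel), \code{n} (channel slots), \code{p_active} (per-slot
#'   expression probability), \code{class} (label), \code{blockable}
#'   (logical: affected by the block, if any).
#' @slot blockOnset Block onset time in s, or \code{NA} for none.
#' @slot blockTimescale Exponential decay timescale of the active-channel
#'   count after onset, s; 0 means instantaneous block.
#' @slot protocol A [VoltageProtocol-class].
#' @slot config A [RecordingConfig-class].
#' @seealso [makeScenario()], [scenarioNames()]
#' @export
setClass("Scenario",
  representation(
    name = "character",
    channelClasses = "list",
    blockOnset = "numeric",
    blockTimescale = "numeric",
    protocol = "VoltageProtocol",
    config = "RecordingConfig"
  )
)

## ---------------------------------------------------------------------------
## Kinetics result containers.
## ---------------------------------------------------------------------------

#' All-points amplitude histogram
#'
#' Histogram of every current sample in a trace at fixed 0.1 pA bin width,
#' normalized to record duration (samples/s per bin), with optional fitted
#' Gaussian mixture components.
#'
#' @slot breaks Bin edges, pA.
#' @slot counts Integer sample counts per bin.
#' @slot density Counts divided by record duration (samples/s).
#' @slot samplingRate Hz.
#' @slot components data.frame(mean, sd, weight) of the fitted mixture
#'   (0 rows before fitting).
#' @seealso [allPointsHistogram()], [fitGaussianMixture()]
#' @export
setClass("AmplitudeHistogram",
  representation(
    breaks = "numeric",
    counts = "numeric",
    density = "numeric",
    samplingRate = "numeric",
    components = "data.frame"
  )
)

setValidity("AmplitudeHistogram", function(object) {
  if (length(object@breaks) != length(object@counts) + 1L)
    return("breaks must have length(counts) + 1")
  if (any(object@counts < 0)) return("counts must be >= 0")
  if (nrow(object@components) &&
      any(object@components$weight < 0)) return("weights must be >= 0")
  TRUE
})

#' Maximum-likelihood dwell-time fit
#'
#' Exponential (mixture) fit to raw dwell durations of one state class.
#' Components are sorted by increasing time constant and their fractions sum
#' to one. For a two-component fit the likelihood-ratio statistic against the
#' one-component fit is carried along.
#'
#' @slot stateClass "open" or "closed".
#' @slot components data.frame(tau_s, fraction), sorted ascending by tau_s.
#' @slot nEvents Number of durations fitted.
#' @slot logLik Maximized log-likelihood.
#' @slot lrtP p-value of the 1-vs-2 component likelihood-ratio test
#'   (NA for a 1-component fit without comparison).
#' @seealso [fitDwellExponentials()], [classifyKineticStates()]
#' @export
setClass("DwellTimeFit",
  representation(
    stateClass = "character",
    components = "data.frame",
    nEvents = "numeric",
    logLik = "numeric",
    lrtP = "numeric"
  )
)

setValidity("DwellTimeFit", function(object) {
  cmp <- object@components
  if (!all(c("tau_s", "fraction") %in% names(cmp)))
    return("components needs tau_s and fraction")
  if (any(cmp$tau_s <= 0)) return("time constants must be > 0")
  if (abs(sum(cmp$fraction) - 1) > 1e-8) return("fractions must sum to 1")
  if (is.unsorted(cmp$tau_s)) return("components must be sorted by tau")
  TRUE
})

## ---------------------------------------------------------------------------
## Ramp analysis containers.
## ---------------------------------------------------------------------------

#' Set of voltage-ramp sweeps
#'
#' Repeated sweeps of a common ramp protocol stored as a samples-by-sweeps
#' matrix, with a per-sweep flag marking sweeps containing channel openings.
#' Event-free sweeps provide the seal-leak/capacitive baseline.
#'
#' @slot sweeps Numeric matrix, one column per sweep, pA.
#' @slot samplingRate Hz.
#' @slot protocol The common [VoltageProtocol-class] (a single ramp segment).
#' @slot openFlags Logical per sweep: openings present.
#' @seealso [simulateRampSet()], [subtractBaselineRamps()]
#' @export
setClass("RampSet",
  representation(
    sweeps = "matrix",
    samplingRate = "numeric",
    protocol = "VoltageProtocol",
    openFlags = "logical"
  )
)

setValidity("RampSet", function(object) {
  if (ncol(object@sweeps) != length(object@openFlags))
    return("one openFlags entry per sweep")
  if (object@samplingRate <= 0) return("samplingRate must be > 0")
  TRUE
})

#' Current-voltage fit result
#'
#' @slot vRev Reversal potential, mV (zero crossing of the fitted line).
#' @slot slopeConductance Slope conductance, pS (non-negative).
#' @slot residualRMS RMS residual of the fit, pA.
#' @seealso [fitIV()]
#' @export
setClass("IVResult",
  representation(
    vRev = "numeric",
    slopeConductance = "numeric",
    residualRMS = "numeric"
  )
)

setValidity("IVResult", function(object) {
  if (object@slopeConductance < 0) return("slopeConductance must be >= 0")
  TRUE
})

## ---------------------------------------------------------------------------
## Electrochemistry containers.
## ---------------------------------------------------------------------------

#' Ionic conditions of the two compartments
#'
#' Per-compartment ion tables (concentration in mM, valence, activity
#' coefficient) for the apical and basolateral baths, plus temperature.
#' Activities are concentration times activity coefficient.
#'
#' @slot apical data.frame(ion, conc_mM, valence, activity_coeff).
#' @slot basolateral data.frame(ion, conc_mM, valence, activity_coeff).
#' @slot temperature Kelvin.
#' @seealso [ionicConditions()], [hbssConditions()], [ghkVrev()]
#' @export
setClass("IonicConditions",
  representation(
    apical = "data.frame",
    basolateral = "data.frame",
    temperature = "numeric"
  )
)

setValidity("IonicConditions", function(object) {
  need <- c("ion", "conc_mM", "valence", "activity_coeff")
  for (side in list(object@apical, object@basolateral)) {
    if (!all(need %in% names(side)))
      return("compartment tables need ion/conc_mM/valence/activity_coeff")
    if (any(side$conc_mM < 0)) return("concentrations must be >= 0")
    if (any(side$activity_coeff <= 0 | side$activity_coeff > 1))
      return("activity coefficients must be in (0, 1]")
  }
  if (object@temperature <= 0) return("temperature must be > 0 K")
  TRUE
})

#' Equivalent-circuit model of the patch configuration
#'
#' Resistances (GOhm) of the conductive pathways seen by a trans-tight
#' junction patch pipette: recording electrode, pipette seal leak, apical
#' membrane channels, claudin-2-dependent and claudin-2-independent
#' paracellular channels, and the monolayer shunt outside the pipette.
#'
#' @slot resistances Named numeric vector, GOhm, all > 0.
#' @slot supportArea Monolayer support area, cm^2.
#' @seealso [circuitModel()], [combinePathways()]
#' @export
setClass("CircuitModel",
  representation(resistances = "numeric", supportArea = "numeric")
)

setValidity("CircuitModel", function(object) {
  if (is.null(names(object@resistances)) || any(names(object@resistances) == ""))
    return("resistances must be named")
  if (any(object@resistances <= 0)) return("resistances must be > 0")
  if (object@supportArea <= 0) return("supportArea must be > 0")
  TRUE
})
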