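#' Voltage protocol constructors
#'
#' \code{holdProtocol} builds a constant-voltage protocol;
#' \code{rampProtocol} builds repeated linear ramps, each optionally preceded
#' by a holding segment (the standard protocol is repetitive 1 s ramps from
#' -100 to +100 mV from a -100 mV holding potential);
#' \code{voltageProtocol} builds one from an explicit segment table.
#'
#' @param voltage_mV Holding voltage, mV.
#' @param duration_s Segment duration, s.
#' @return A [VoltageProtocol-class].
#' @examples
#' holdProtocol(-100, 30)
#' rampProtocol(nSweeps = 4)
#' @export
holdProtocol <- function(voltage_mV, duration_s) {
  voltageProtocol(data.frame(kind = "hold", start_mV = voltage_mV,
                             end_mV = voltage_mV, duration_s = duration_s))
}

#' @rdname holdProtocol
#' @param from_mV,to_mV Ramp start and end voltage, mV.
#' @param ramp_s Ramp duration, s.
#' @param hold_mV Holding voltage between ramps, mV.
#' @param hold_s Holding duration before each ramp, s (0 for none).
#' @param nSweeps Number of ramp repetitions.
#' @export
rampProtocol <- function(from_mV = -100, to_mV = 100, ramp_s = 1,
                         hold_mV = -100, hold_s = 0.5, nSweeps = 1) {
  one <- data.frame(kind = c("hold", "ramp"),
                    start_mV = c(hold_mV, from_mV),
                    end_mV = c(hold_mV, to_mV),
                    duration_s = c(hold_s, ramp_s))
  if (hold_s <= 0) one <- one[one$kind == "ramp", , drop = FALSE]
  voltageProtocol(do.call(rbind, replicate(nSweeps, one, simplify = FALSE)))
}

#' @rdname holdProtocol
#' @param segments data.frame(kind, start_mV, end_mV, duration_s).
#' @export
voltageProtocol <- function(segments) {
  rownames(segments) <- NULL
  new("VoltageProtocol", segments = segments)
}

#' Total protocol duration
#'
#' @param protocol A [VoltageProtocol-class].
#' @return Duration in s.
#' @export
protocolDuration <- function(protocol) {
  sum(protocol@segments$duration_s)
}

#' Command voltage at given times
#'
#' Evaluates the piecewise hold/ramp protocol. Times beyond the protocol end
#' hold the final voltage.
#'
#' @param protocol A [VoltageProtocol-class].
#' @param times_s Numeric vector of times, s.
#' @return Voltage in mV at each time.
#' @examples
#' protocolVoltage(rampProtocol(hold_s = 0), c(0, 0.5, 1))
#' @export
protocolVoltage <- function(protocol, times_s) {
  s <- protocol@segments
  ends <- cumsum(s$duration_s)
  starts <- c(0, ends[-length(ends)])
  idx <- findInterval(times_s, starts, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(s)] <- nrow(s)
  frac <- (times_s - starts[idx]) / s$duration_s[idx]
  frac <- pmin(pmax(frac, 0), 1)
  ifelse(s$kind[idx] == "hold",
         s$start_mV[idx],
         s$start_mV[idx] + frac * (s$end_mV[idx] - s$start_mV[idx]))
}

#' Split a trace into per-segment traces
#'
#' Cuts a trace at its protocol segment boundaries, returning one
#' [CurrentTrace-class] per segment with a single-segment protocol. Needed
#' whenever baseline estimation or event detection must run per holding
#' potential (e.g. off-junction records held first at -100 then at +100 mV,
#' where the seal-leak offset changes sign between segments).
#'
#' @param trace A [CurrentTrace-class].
#' @return List of [CurrentTrace-class], one per protocol segment.
#' @export
splitBySegments <- function(trace) {
  stopifnot(is(trace, "CurrentTrace"))
  s <- trace@protocol@segments
  fs <- trace@samplingRate
  ends <- round(cumsum(s$duration_s) * fs)
  starts <- c(0, head(ends, -1L)) + 1L
  ends <- pmin(ends, length(trace@current))
  lapply(seq_len(nrow(s)), function(i) {
    if (starts[i] > ends[i]) return(NULL)
    new("CurrentTrace",
        current = trace@current[starts[i]:ends[i]],
        samplingRate = fs,
        protocol = voltageProtocol(s[i, , drop = FALSE]),
        metadata = utils::modifyList(trace@metadata, list(segment = i)))
  })
}

#' Recording configuration constructor
#'
#' Defaults emulate the standard recording system: 25 kHz sampling with
#' 5 kHz 4-pole Bessel low-pass filtering, 0.6 pA baseline noise, a 30 GOhm
#' seal leak and 30 s records at physiological temperature (scale 1).
#'
#' @param samplingRate Hz.
#' @param filterCutoff Hz.
#' @param noiseSD pA.
#' @param sealResistance GOhm (\code{Inf} disables the leak).
#' @param duration s.
#' @param temperatureScale Multiplier on gating rates and expected active
#'   channel count (1 = 37 degrees C; ~0.63 emulates cooling to 15 degrees C).
#' @return A [RecordingConfig-class].
#' @examples
#' recordingConfig(duration = 10)
#' @export
recordingConfig <- function(samplingRate = 25000, filterCutoff = 5000,
                            noiseSD = 0.6, sealResistance = 30,
                            duration = 30, temperatureScale = 1) {
  new("RecordingConfig",
      samplingRate = samplingRate, filterCutoff = filterCutoff,
      noiseSD = noiseSD, sealResistance = sealResistance,
      duration = duration, temperatureScale = temperatureScale)
}
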