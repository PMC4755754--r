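#' Simulate a set of voltage-ramp sweeps
#'
#' Generates repeated 1 s voltage ramps (default -100 to +100 mV) across a
#' simulated channel, rendered at an oversampled internal rate and
#' block-averaged down to the output sampling rate, emulating 100 kHz
#' oversampling averaged to 10 kHz. The gating path runs continuously across
#' sweeps. Sweeps containing ground-truth openings are flagged.
#'
#' @param model A [GatingModel-class] (default [claudin2Model()]).
#' @param nSweeps Number of ramp repetitions.
#' @param nChannels Channels carried in the patch.
#' @param seed Integer seed.
#' @param config A [RecordingConfig-class]; default 10 kHz output with 5 kHz
#'   Bessel filtering and 0.4 pA noise.
#' @param from_mV,to_mV,ramp_s Ramp shape.
#' @param oversample Internal oversampling factor (default 10).
#' @return A [RampSet-class].
#' @examples
#' rs <- simulateRampSet(nSweeps = 5, seed = 1)
#' @export
simulateRampSet <- function(model = claudin2Model(), nSweeps = 20,
                            nChannels = 1, seed = NULL, config = NULL,
                            from_mV = -100, to_mV = 100, ramp_s = 1,
                            oversample = 10L) {
  if (!is.null(seed)) set.seed(seed)
  total_s <- nSweeps * ramp_s
  if (is.null(config))
    config <- recordingConfig(samplingRate = 10000, filterCutoff = 5000,
                              noiseSD = 0.4, duration = total_s)
  proto <- rampProtocol(from_mV = from_mV, to_mV = to_mV, ramp_s = ramp_s,
                        hold_s = 0, nSweeps = nSweeps)
  paths <- replicate(nChannels, simulateStatePath(model, total_s),
                     simplify = FALSE)
  trace <- renderCurrent(paths, proto, config, model, oversample = oversample,
                         metadata = list(kind = "rampset"))
  x <- currentSamples(trace)
  perSweep <- round(ramp_s * config@samplingRate)
  sweeps <- matrix(x[seq_len(perSweep * nSweeps)], nrow = perSweep)

  openFlags <- vapply(seq_len(nSweeps), function(s) {
    lo <- (s - 1) * ramp_s; hi <- s * ramp_s
    any(vapply(paths, function(p) {
      op <- p[p$class == "open", , drop = FALSE]
      any(op$start_s < hi & op$start_s + op$duration_s > lo)
    }, logical(1)))
  }, logical(1))

  new("RampSet", sweeps = sweeps, samplingRate = config@samplingRate,
      protocol = rampProtocol(from_mV = from_mV, to_mV = to_mV,
                              ramp_s = ramp_s, hold_s = 0, nSweeps = 1),
      openFlags = openFlags)
}

#' Voltage axis of a ramp set
#'
#' @param rampSet A [RampSet-class].
#' @return Command voltage (mV) at each sample of one sweep.
#' @export
rampVoltage <- function(rampSet) {
  n <- nrow(rampSet@sweeps)
  protocolVoltage(rampSet@protocol, (seq_len(n) - 0.5) / rampSet@samplingRate)
}

#' Subtract event-free sweeps from event-containing sweeps
#'
#' Pointwise subtraction of the mean event-free sweep from every
#' event-containing sweep, removing seal-leak and capacitive components and
#' leaving event-only current. Samples during openings are marked by a
#' half-amplitude criterion with a voltage-scaled threshold
#' (\eqn{0.5\,\gamma |V - V_{rev}|/1000}, floored near the reversal
#' potential at four times the robust noise SD) sustained for at least
#' \code{minDuration}.
#'
#' @param rampSet A [RampSet-class].
#' @param conductance_pS Expected unitary conductance used to scale the
#'   half-amplitude threshold.
#' @param vRev_mV Assumed reversal potential for the threshold scaling.
#' @param minDuration Shortest opening retained, ms.
#' @return data.frame(v_mV, i_pA, sweep, open): one row per sample of each
#'   event-containing sweep; \code{open} marks event samples.
#' @export
subtractBaselineRamps <- function(rampSet, conductance_pS = 90, vRev_mV = 0,
                                  minDuration = 0.2) {
  stopifnot(is(rampSet, "RampSet"))
  flags <- rampSet@openFlags
  if (!any(!flags)) stop("no event-free sweep available for subtraction")
  if (!any(flags)) stop("no event-containing sweep to subtract from")
  base <- rowMeans(rampSet@sweeps[, !flags, drop = FALSE])
  v <- rampVoltage(rampSet)
  minSamples <- max(1L, round(minDuration / 1000 * rampSet@samplingRate))
  out <- lapply(which(flags), function(s) {
    res <- rampSet@sweeps[, s] - base
    ## first-difference noise estimate: insensitive to events and to any
    ## smooth residual slope across the sweep
    noise <- stats::mad(diff(res)) / sqrt(2)
    thr <- pmax(0.5 * abs(.pA_from_pS_mV(conductance_pS, v - vRev_mV)),
                4 * noise)
    mask <- abs(res) > thr
    r <- rle(mask)
    r$values[r$values & r$lengths < minSamples] <- FALSE
    mask <- inverse.rle(r)
    ## drop two samples at each event edge (filter transients bias the fit);
    ## events too short to have an unbiased interior are excluded entirely
    r <- rle(mask)
    ends <- cumsum(r$lengths); starts <- c(1L, head(ends, -1L) + 1L)
    for (k in which(r$values)) {
      if (r$lengths[k] > 4L) {
        mask[starts[k] + 0:1] <- FALSE
        mask[ends[k] - 0:1] <- FALSE
      } else {
        mask[starts[k]:ends[k]] <- FALSE
      }
    }
    data.frame(v_mV = v, i_pA = res, sweep = s, open = mask)
  })
  do.call(rbind, out)
}

#' Fit a line to event current-voltage samples
#'
#' Least-squares line through event-only I-V samples; the reversal potential
#' is the zero crossing and the slope conductance is the slope converted to
#' pS. When the input carries an \code{open} column (from
#' [subtractBaselineRamps()]) only open samples enter the fit.
#'
#' @param points data.frame with \code{v_mV} and \code{i_pA} (and optionally
#'   \code{open}).
#' @return An [IVResult-class].
#' @examples
#' v <- seq(-100, 100, by = 10)
#' fitIV(data.frame(v_mV = v, i_pA = 0.09 * v))  # 90 pS through 0 mV
#' @export
fitIV <- function(points) {
  if (!all(c("v_mV", "i_pA") %in% names(points)))
    stop("points needs v_mV and i_pA columns")
  if ("open" %in% names(points)) points <- points[points$open, , drop = FALSE]
  if (length(unique(points$v_mV)) < 2L)
    stop("need at least two voltage-distinct points")
  fit <- stats::lm(i_pA ~ v_mV, data = points)
  co <- stats::coef(fit)
  slope <- co[["v_mV"]]
  if (!is.finite(slope) ||
      abs(slope) * diff(range(points$v_mV)) < 1e-12 * (1 + abs(co[[1L]])))
    stop("degenerate current-voltage relationship (zero slope)")
  vr <- -co[["(Intercept)"]] / slope
  rms <- sqrt(mean(stats::residuals(fit)^2))
  new("IVResult", vRev = vr, slopeConductance = abs(slope) * 1000,
      residualRMS = rms)
}

#' Unitary conductance from event amplitude and driving force
#'
#' @param amplitude Event amplitude, pA.
#' @param v Holding potential, mV.
#' @param vRev Reversal potential, mV (must differ from \code{v}).
#' @return Conductance in pS, sign-normalized positive:
#'   \code{1000 * amplitude / (v - vRev)}.
#' @examples
#' eventConductance(-9, -100, 0)  # 90 pS
#' @export
eventConductance <- function(amplitude, v, vRev = 0) {
  if (any(v == vRev)) stop("holding potential equals reversal potential")
  abs(1000 * amplitude / (v - vRev))
}
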