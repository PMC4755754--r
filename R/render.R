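#' Render a current trace from channel state paths
#'
#' Converts per-channel gating trajectories into a sampled, filtered current
#' trace. The instantaneous current is the sum over channels of
#' \eqn{\gamma (V - V_{rev})/1000} (pA, with conductance in pS and voltage in
#' mV) for the state occupied at each instant, plus the seal-leak current
#' \eqn{V/R_{seal}} (pA, with resistance in GOhm) and additive Gaussian
#' noise; the sum is low-pass filtered at the configured cutoff and, when
#' rendered at an oversampled rate, block-averaged down to the output
#' sampling rate. Negative current corresponds to cations moving towards the
#' recording electrode, so an open 90 pS channel at -100 mV renders as a
#' -9 pA deflection.
#'
#' \code{noiseSD} in the configuration is the baseline noise SD of the
#' \emph{filtered} output; the white noise injected before the filter is
#' scaled up accordingly.
#'
#' @param paths List of state paths (from [simulateStatePath()]), one per
#'   channel; may be empty for a channel-free recording.
#' @param protocol A [VoltageProtocol-class]; every path must cover its
#'   duration.
#' @param config A [RecordingConfig-class].
#' @param model A [GatingModel-class], or a list of models (one per path).
#' @param seed Optional integer seed for the noise generator.
#' @param oversample Integer; render internally at
#'   \code{oversample * samplingRate} and block-average down.
#' @param metadata Named list stored in the trace.
#' @return A [CurrentTrace-class].
#' @examples
#' m <- claudin2Model()
#' p <- simulateStatePath(m, 2, seed = 1)
#' tr <- renderCurrent(list(p), holdProtocol(-100, 2),
#'                     recordingConfig(duration = 2), m, seed = 1)
#' @export
renderCurrent <- function(paths, protocol, config, model,
                          seed = NULL, oversample = 1L, metadata = list()) {
  stopifnot(is(protocol, "VoltageProtocol"), is(config, "RecordingConfig"))
  validObject(config)
  if (!is.null(seed)) set.seed(seed)
  dur <- protocolDuration(protocol)
  models <- if (is(model, "GatingModel")) rep(list(model), length(paths))
            else model
  if (length(paths) && length(models) != length(paths))
    stop("need one model per path")
  for (p in paths) {
    if (sum(p$duration_s) < dur * (1 - 1e-9))
      stop("path does not cover the protocol duration")
  }
  oversample <- as.integer(oversample)
  fsInt <- config@samplingRate * oversample
  n <- round(dur * fsInt)
  if (n < 1L) stop("empty record")
  times <- (seq_len(n) - 0.5) / fsInt      # mid-sample times
  v <- protocolVoltage(protocol, times)

  total <- numeric(n)
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    m <- models[[i]]
    g <- m@poreConductance[match(p$state, m@stateLabels)]
    idx <- findInterval(times, p$start_s)
    idx[idx < 1L] <- 1L
    total <- total + .pA_from_pS_mV(g[idx], v - m@reversalPotential)
  }
  if (is.finite(config@sealResistance))
    total <- total + .pA_from_mV_GOhm(v, config@sealResistance)

  if (config@noiseSD > 0) {
    gn <- .filterNoiseGain(config@filterCutoff, fsInt)
    total <- total + stats::rnorm(n, sd = config@noiseSD / gn)
  }
  filtered <- besselLowpass(total, config@filterCutoff, fsInt)
  if (oversample > 1L) filtered <- decimateByAveraging(filtered, oversample)

  md <- metadata
  if (is.null(md$seed)) md$seed <- seed
  md$filterCutoff <- config@filterCutoff
  new("CurrentTrace",
      current = filtered,
      samplingRate = config@samplingRate,
      protocol = protocol,
      metadata = md)
}

## White-noise attenuation factor of the Bessel stage: ratio of output to
## input SD for white Gaussian input, from the impulse response energy.
.filterNoiseGain <- function(cutoff_Hz, samplingRate) {
  co <- besselLowpassCoefficients(cutoff_Hz, samplingRate)
  nImp <- max(64L, ceiling(20 * samplingRate / cutoff_Hz))
  h <- as.numeric(signal::filter(signal::Arma(b = co$b, a = co$a),
                                 c(1, numeric(nImp - 1L))))
  sqrt(sum(h^2))
}

#' Re-filter a trace at a lower cutoff
#'
#' Applies an additional 4-pole Bessel low-pass stage to an existing trace,
#' e.g. the 500 Hz filtering needed to resolve sub-2 pA off-junction
#' membrane events.
#'
#' @param trace A [CurrentTrace-class].
#' @param cutoff_Hz New -3 dB cutoff, Hz.
#' @return A filtered [CurrentTrace-class].
#' @export
refilterTrace <- function(trace, cutoff_Hz) {
  stopifnot(is(trace, "CurrentTrace"))
  y <- besselLowpass(trace@current, cutoff_Hz, trace@samplingRate)
  new("CurrentTrace", current = y, samplingRate = trace@samplingRate,
      protocol = trace@protocol,
      metadata = utils::modifyList(trace@metadata,
                                   list(refilteredAt = cutoff_Hz)))
}
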