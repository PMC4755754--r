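## Generics and accessors. Slots are never accessed directly by user code.

#' @rdname CurrentTrace-class
#' @param object,x A package object.
#' @export
setGeneric("currentSamples", function(x) standardGeneric("currentSamples"))

#' @rdname CurrentTrace-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname CurrentTrace-class
#' @export
setGeneric("protocol", function(x) standardGeneric("protocol"))

#' @rdname CurrentTrace-class
#' @export
setGeneric("traceMetadata", function(x) standardGeneric("traceMetadata"))

#' @rdname CurrentTrace-class
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))

#' @rdname IdealizedRecord-class
#' @export
setGeneric("dwells", function(x) standardGeneric("dwells"))

#' @rdname IdealizedRecord-class
#' @export
setGeneric("totalTime", function(x) standardGeneric("totalTime"))

#' @rdname IdealizedRecord-class
#' @export
setGeneric("baseline", function(x) standardGeneric("baseline"))

#' @rdname IdealizedRecord-class
#' @param x An \code{IdealizedRecord}.
#' @export
setGeneric("openDwells", function(x) standardGeneric("openDwells"))

#' @rdname IdealizedRecord-class
#' @export
setGeneric("closedDwells", function(x) standardGeneric("closedDwells"))

#' @rdname GatingModel-class
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))

#' @rdname GatingModel-class
#' @export
setGeneric("stateClasses", function(x) standardGeneric("stateClasses"))

#' @rdname GatingModel-class
#' @export
setGeneric("transitionRates", function(x) standardGeneric("transitionRates"))

#' @rdname GatingModel-class
#' @export
setGeneric("poreConductance", function(x) standardGeneric("poreConductance"))

#' @rdname GatingModel-class
#' @export
setGeneric("reversalPotential", function(x) standardGeneric("reversalPotential"))

#' @rdname DwellTimeFit-class
#' @export
setGeneric("timeConstants", function(x) standardGeneric("timeConstants"))

#' @rdname DwellTimeFit-class
#' @export
setGeneric("componentTable", function(x) standardGeneric("componentTable"))

## --- CurrentTrace accessors -------------------------------------------------

#' @rdname CurrentTrace-class
#' @export
setMethod("currentSamples", "CurrentTrace", function(x) x@current)

#' @rdname CurrentTrace-class
#' @export
setMethod("samplingRate", "CurrentTrace", function(x) x@samplingRate)

#' @rdname CurrentTrace-class
#' @export
setMethod("protocol", "CurrentTrace", function(x) x@protocol)

#' @rdname CurrentTrace-class
#' @export
setMethod("traceMetadata", "CurrentTrace", function(x) x@metadata)

#' @rdname CurrentTrace-class
#' @export
setMethod("traceTimes", "CurrentTrace", function(x)
  (seq_along(x@current) - 1) / x@samplingRate)

#' @rdname RampSet-class
#' @export
setMethod("samplingRate", "RampSet", function(x) x@samplingRate)

#' @rdname RampSet-class
#' @export
setMethod("protocol", "RampSet", function(x) x@protocol)

#' @rdname AmplitudeHistogram-class
#' @export
setMethod("samplingRate", "AmplitudeHistogram", function(x) x@samplingRate)

## --- IdealizedRecord accessors ---------------------------------------------

#' @rdname IdealizedRecord-class
#' @export
setMethod("dwells", "IdealizedRecord", function(x) x@dwells)

#' @rdname IdealizedRecord-class
#' @export
setMethod("totalTime", "IdealizedRecord", function(x) x@totalTime)

#' @rdname IdealizedRecord-class
#' @export
setMethod("baseline", "IdealizedRecord", function(x) x@baseline)

#' @rdname IdealizedRecord-class
#' @export
setMethod("openDwells", "IdealizedRecord", function(x)
  x@dwells[x@dwells$level >= 1L, , drop = FALSE])

#' @rdname IdealizedRecord-class
#' @export
setMethod("closedDwells", "IdealizedRecord", function(x)
  x@dwells[x@dwells$level == 0L, , drop = FALSE])

## --- GatingModel accessors ---------------------------------------------------

#' @rdname GatingModel-class
#' @export
setMethod("stateLabels", "GatingModel", function(x) x@stateLabels)

#' @rdname GatingModel-class
#' @export
setMethod("stateClasses", "GatingModel", function(x) x@stateClass)

#' @rdname GatingModel-class
#' @export
setMethod("transitionRates", "GatingModel", function(x) x@rates)

#' @rdname GatingModel-class
#' @export
setMethod("poreConductance", "GatingModel", function(x) x@poreConductance)

#' @rdname GatingModel-class
#' @export
setMethod("reversalPotential", "GatingModel", function(x) x@reversalPotential)

## --- DwellTimeFit accessors --------------------------------------------------

#' @rdname DwellTimeFit-class
#' @export
setMethod("timeConstants", "DwellTimeFit", function(x) x@components$tau_s)

#' @rdname DwellTimeFit-class
#' @export
setMethod("componentTable", "DwellTimeFit", function(x) x@components)

#' @rdname IVResult-class
#' @export
setGeneric("vRev", function(x) standardGeneric("vRev"))

#' @rdname IVResult-class
#' @export
setGeneric("slopeConductance", function(x) standardGeneric("slopeConductance"))

#' @rdname IVResult-class
#' @export
setMethod("vRev", "IVResult", function(x) x@vRev)

#' @rdname IVResult-class
#' @export
setMethod("slopeConductance", "IVResult", function(x) x@slopeConductance)

## --- show methods ------------------------------------------------------------

setMethod("show", "GatingModel", function(object) {
  cat("GatingModel with", length(object@stateLabels), "states\n")
  cat("  states:",
      paste0(object@stateLabels, " (", object@stateClass, ")", collapse = ", "),
      "\n")
  g <- object@poreConductance[object@stateClass == "open"]
  cat("  open-state conductance (pS):", paste(g, collapse = ", "), "\n")
  cat("  reversal potential (mV):", object@reversalPotential, "\n")
})

setMethod("show", "CurrentTrace", function(object) {
  dur <- length(object@current) / object@samplingRate
  cat(sprintf("CurrentTrace: %d samples, %.4g s at %.4g kHz\n",
              length(object@current), dur, object@samplingRate / 1000))
  if (!is.null(object@metadata$scenario))
    cat("  scenario:", object@metadata$scenario, "\n")
})

setMethod("show", "IdealizedRecord", function(object) {
  op <- openDwells(object)
  cat(sprintf("IdealizedRecord: %d dwells (%d open) over %.4g s, baseline %.3g pA\n",
              nrow(object@dwells), nrow(op), object@totalTime, object@baseline))
})

setMethod("show", "DwellTimeFit", function(object) {
  cat(sprintf("DwellTimeFit (%s): %d component(s), n = %d\n",
              object@stateClass, nrow(object@components), object@nEvents))
  cmp <- object@components
  for (i in seq_len(nrow(cmp)))
    cat(sprintf("  tau = %.4g ms (fraction %.3f)\n",
                1000 * cmp$tau_s[i], cmp$fraction[i]))
})

setMethod("show", "IVResult", function(object) {
  cat(sprintf("IVResult: V_rev = %.3g mV, slope = %.4g pS (RMS %.3g pA)\n",
              object@vRev, object@slopeConductance, object@residualRMS))
})

setMethod("show", "AmplitudeHistogram", function(object) {
  cat(sprintf("AmplitudeHistogram: %d bins of %.2g pA, %d samples\n",
              length(object@counts), diff(object@breaks[1:2]),
              sum(object@counts)))
  if (nrow(object@components)) {
    cat("  fitted components (mean pA / sd pA / weight):\n")
    with(object@components, for (i in seq_along(mean))
      cat(sprintf("    %.3g / %.3g / %.3f\n", mean[i], sd[i], weight[i])))
  }
})

setMethod("show", "Scenario", function(object) {
  cat("Scenario:", object@name, "\n")
  for (cc in object@channelClasses)
    cat(sprintf("  %s: %d slot(s), p_active %.3g\n",
                cc$class, cc$n, cc$p_active))
  if (is.finite(object@blockOnset))
    cat(sprintf("  block at %.3g s (timescale %.3g s)\n",
                object@blockOnset, object@blockTimescale))
})
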