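## Physical constants and unit conversions used package-wide.
## Units are fixed throughout: current pA, voltage mV, conductance pS,
## resistance GOhm (areal resistance Ohm.cm2), time s (dwell times reported
## in ms where stated), concentration mM, temperature K.

.GAS_CONSTANT <- 8.31446261815324    # J mol^-1 K^-1
.FARADAY <- 96485.33212              # C mol^-1

#' Thermal voltage RT/F
#'
#' @param temperature Temperature in kelvin.
#' @return RT/F in millivolts.
#' @examples
#' thermalVoltage(310.15) # ~26.7 mV at 37 degrees C
#' @export
thermalVoltage <- function(temperature = 310.15) {
  stopifnot(is.numeric(temperature), temperature > 0)
  1000 * .GAS_CONSTANT * temperature / .FARADAY
}

## pA = pS * mV / 1000 ; pA = mV / GOhm
.pA_from_pS_mV <- function(g_pS, v_mV) g_pS * v_mV / 1000
.pA_from_mV_GOhm <- function(v_mV, r_GOhm) v_mV / r_GOhm
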