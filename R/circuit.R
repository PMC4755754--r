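#' Ohm's-law resistance and current for single-channel pathways
#'
#' \code{ohmicResistance} converts an event current at a holding potential
#' into a pathway resistance (GOhm); \code{pathwayCurrent} is the inverse.
#' A 9 pA event at 100 mV corresponds to about 11 GOhm, a 4 pA event to
#' 25 GOhm, a 2 pA event to 50 GOhm.
#'
#' @param current_pA Event or steady-state current, pA (nonzero).
#' @param voltage_mV Holding potential, mV.
#' @param digits Optional significant digits for reporting (e.g. 2, as used
#'   when quoting pathway resistances); \code{NULL} returns the exact value.
#' @return Resistance in GOhm (positive).
#' @examples
#' ohmicResistance(9, 100, digits = 2)   # 11
#' ohmicResistance(3.5, 100, digits = 1) # 30
#' @export
ohmicResistance <- function(current_pA, voltage_mV, digits = NULL) {
  if (any(current_pA == 0)) stop("zero current")
  r <- abs(voltage_mV / current_pA)
  if (!is.null(digits)) r <- signif(r, digits)
  r
}

#' @rdname ohmicResistance
#' @param resistance_GOhm Pathway resistance, GOhm (nonzero).
#' @return \code{pathwayCurrent}: current in pA.
#' @examples
#' pathwayCurrent(25, 100)  # 4 pA
#' @export
pathwayCurrent <- function(resistance_GOhm, voltage_mV) {
  if (any(resistance_GOhm == 0)) stop("zero resistance")
  voltage_mV / resistance_GOhm
}

#' Convert areal resistance to absolute resistance
#'
#' @param r_areal_ohm_cm2 Areal resistance, Ohm.cm^2.
#' @param area_cm2 Support area, cm^2 (> 0).
#' @return Absolute resistance in MOhm (1500 Ohm.cm^2 on 0.33 cm^2 is about
#'   0.0045 MOhm).
#' @examples
#' arealToAbsolute(1500, 0.33)
#' @export
arealToAbsolute <- function(r_areal_ohm_cm2, area_cm2) {
  if (any(area_cm2 <= 0)) stop("area must be > 0")
  (r_areal_ohm_cm2 / area_cm2) / 1e6
}

#' Equivalent-circuit model of the trans-tight junction patch
#'
#' Default pathway resistances reflect the measured configuration: a 2.5
#' MOhm electrode, ~30 GOhm pipette seal leak, 50 GOhm apical membrane
#' channel pathway (2 pA at 100 mV), 11 GOhm claudin-2 channel (9 pA at
#' 100 mV), 25 GOhm claudin-2-independent channel (4 pA at 100 mV) and a
#' monolayer shunt of 1500 Ohm.cm^2 on the 0.33 cm^2 support (0.0045 MOhm;
#' negligible against every other pathway).
#'
#' @param electrode,seal_leak,apical_membrane_path,cldn2_channel,independent_channel,monolayer_shunt
#'   Pathway resistances, GOhm.
#' @param supportArea Support area, cm^2.
#' @return A [CircuitModel-class].
#' @examples
#' circuitModel()
#' @export
circuitModel <- function(electrode = 2.5e-3,
                         seal_leak = 30,
                         apical_membrane_path = 50,
                         cldn2_channel = 11,
                         independent_channel = 25,
                         monolayer_shunt = arealToAbsolute(1500, 0.33) / 1000,
                         supportArea = 0.33) {
  new("CircuitModel",
      resistances = c(electrode = electrode, seal_leak = seal_leak,
                      apical_membrane_path = apical_membrane_path,
                      cldn2_channel = cldn2_channel,
                      independent_channel = independent_channel,
                      monolayer_shunt = monolayer_shunt),
      supportArea = supportArea)
}

#' Combine circuit pathways in series or parallel
#'
#' @param circuit A [CircuitModel-class].
#' @param mode "series" or "parallel".
#' @param subset Names of the pathways to combine.
#' @return Combined resistance, GOhm.
#' @examples
#' cm <- circuitModel()
#' combinePathways(cm, "series", c("electrode", "cldn2_channel")) # ~11.0025
#' @export
combinePathways <- function(circuit, mode = c("series", "parallel"), subset) {
  stopifnot(is(circuit, "CircuitModel"))
  mode <- match.arg(mode)
  if (!length(subset)) stop("subset must be non-empty")
  missing <- setdiff(subset, names(circuit@resistances))
  if (length(missing)) stop("unknown pathways: ", paste(missing, collapse = ", "))
  r <- circuit@resistances[subset]
  if (mode == "series") sum(r) else 1 / sum(1 / r)
}
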