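## Ionic-condition tables for permeability calculations. Only Na+, Cl- and
## at most one substituted monovalent test cation enter the GHK algebra;
## minor buffer ions are ignored.

## NaCl activity coefficients at the three bench concentrations; other
## concentrations are interpolated log-linearly in concentration.
.NACL_ACTIVITY <- data.frame(conc_mM = c(13.5, 67.5, 135),
                             coeff = c(0.882, 0.812, 0.755))

#' NaCl activity coefficient
#'
#' Activity coefficients of 0.755, 0.812 and 0.882 at 135, 67.5 and 13.5 mM
#' NaCl, interpolated log-linearly in concentration between these anchors
#' and clamped outside them.
#'
#' @param conc_mM NaCl concentration, mM.
#' @return Activity coefficient in (0, 1].
#' @examples
#' naclActivityCoefficient(c(13.5, 135))
#' @export
naclActivityCoefficient <- function(conc_mM) {
  stopifnot(all(conc_mM > 0))
  stats::approx(log(.NACL_ACTIVITY$conc_mM), .NACL_ACTIVITY$coeff,
                xout = log(conc_mM), rule = 2)$y
}

#' Construct ionic conditions
#'
#' \code{ionicConditions} builds the container from explicit per-compartment
#' ion tables. \code{naclConditions} builds symmetric or diluted NaCl baths
#' (dilution replaces NaCl iso-osmotically with mannitol, which carries no
#' charge and is omitted). \code{biionicConditions} replaces all basolateral
#' NaCl with a chloride salt of a substituted monovalent test cation.
#'
#' @param apical,basolateral data.frame(ion, conc_mM, valence,
#'   activity_coeff).
#' @param temperature Kelvin (default 310.15, i.e. 37 degrees C).
#' @return An [IonicConditions-class].
#' @export
ionicConditions <- function(apical, basolateral, temperature = 310.15) {
  new("IonicConditions", apical = apical, basolateral = basolateral,
      temperature = temperature)
}

.naclSide <- function(nacl_mM) {
  co <- naclActivityCoefficient(nacl_mM)
  data.frame(ion = c("Na", "Cl"), conc_mM = nacl_mM,
             valence = c(1L, -1L), activity_coeff = co,
             stringsAsFactors = FALSE)
}

#' @rdname ionicConditions
#' @param apical_mM,basolateral_mM NaCl concentration per compartment, mM.
#' @export
naclConditions <- function(apical_mM = 135, basolateral_mM = 135,
                           temperature = 310.15) {
  ionicConditions(.naclSide(apical_mM), .naclSide(basolateral_mM),
                  temperature)
}

#' @rdname ionicConditions
#' @param cation Name of the substituted basolateral cation (e.g. "MA",
#'   "TMA", "NMDG").
#' @param salt_mM Salt concentration, mM (both compartments).
#' @param activity_coeff Activity coefficient of the substituted salt;
#'   defaults to the NaCl value at the same concentration.
#' @export
biionicConditions <- function(cation = "MA", salt_mM = 135,
                              activity_coeff = NULL,
                              temperature = 310.15) {
  if (is.null(activity_coeff)) activity_coeff <- naclActivityCoefficient(salt_mM)
  baso <- data.frame(ion = c(cation, "Cl"), conc_mM = salt_mM,
                     valence = c(1L, -1L),
                     activity_coeff = c(activity_coeff,
                                        naclActivityCoefficient(salt_mM)),
                     stringsAsFactors = FALSE)
  ionicConditions(.naclSide(salt_mM), baso, temperature)
}

## Activity (mM) of one ion in one compartment; 0 when absent.
.ionActivity <- function(side, ion, useActivities = TRUE) {
  i <- match(ion, side$ion)
  if (is.na(i)) return(0)
  side$conc_mM[i] * if (useActivities) side$activity_coeff[i] else 1
}
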