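#' Transepithelial resistance from current-clamp pulses
#'
#' Ohm's-law TER: voltage deflection over current step, scaled by the
#' monolayer support area.
#'
#' @param deltaV_mV Voltage deflection, mV.
#' @param deltaI_uA Current step, microamperes (nonzero).
#' @param area_cm2 Support area, cm^2.
#' @return Areal resistance in Ohm.cm^2.
#' @examples
#' terFromPulses(1, 10, 0.33)  # 33 Ohm.cm2
#' @export
terFromPulses <- function(deltaV_mV, deltaI_uA, area_cm2) {
  if (any(deltaI_uA == 0)) stop("zero current step")
  ## mV / uA = kOhm; x1000 -> Ohm
  (deltaV_mV / deltaI_uA) * 1000 * area_cm2
}

#' Goldman-Hodgkin-Katz reversal potential
#'
#' Reversal potential of a monovalent Na+/Cl- (plus at most one substituted
#' test cation) system:
#' \deqn{V_{rev} = \frac{RT}{F} \ln
#'   \frac{P_{Na} a_{Na,b} + P_X a_{X,b} + P_{Cl} a_{Cl,a}}
#'        {P_{Na} a_{Na,a} + P_X a_{X,a} + P_{Cl} a_{Cl,b}}}
#' with \eqn{V = V_{apical} - V_{basal}} and activities
#' \eqn{a = \gamma c} by default. Permeabilities are expressed relative to
#' chloride (\eqn{P_{Cl} = 1}).
#'
#' @param conditions An [IonicConditions-class].
#' @param pNaPCl Na-to-Cl permeability ratio.
#' @param pXPNa Permeability of the substituted cation relative to Na
#'   (ignored when no third ion is present).
#' @param useActivities Use activities (default) or bare concentrations.
#' @return Reversal potential, mV.
#' @examples
#' ghkVrev(naclConditions(), pNaPCl = 9.5)          # symmetric: 0 mV
#' ghkVrev(naclConditions(13.5, 135), pNaPCl = 9.5) # dilution potential
#' @export
ghkVrev <- function(conditions, pNaPCl, pXPNa = 1, useActivities = TRUE) {
  stopifnot(is(conditions, "IonicConditions"), pNaPCl >= 0)
  api <- conditions@apical; baso <- conditions@basolateral
  xIon <- setdiff(unique(c(api$ion, baso$ion)), c("Na", "Cl"))
  if (length(xIon) > 1L) stop("at most one substituted cation supported")
  pX <- if (length(xIon)) pXPNa * pNaPCl else 0
  aNaA <- .ionActivity(api, "Na", useActivities)
  aNaB <- .ionActivity(baso, "Na", useActivities)
  aClA <- .ionActivity(api, "Cl", useActivities)
  aClB <- .ionActivity(baso, "Cl", useActivities)
  aXA <- if (length(xIon)) .ionActivity(api, xIon, useActivities) else 0
  aXB <- if (length(xIon)) .ionActivity(baso, xIon, useActivities) else 0
  num <- pNaPCl * aNaB + pX * aXB + aClA
  den <- pNaPCl * aNaA + pX * aXA + aClB
  if (den <= 0 || num <= 0) stop("non-positive GHK numerator or denominator")
  thermalVoltage(conditions@temperature) * log(num / den)
}

#' Invert the GHK equation for a dilution potential
#'
#' Finds the Na/Cl permeability ratio whose GHK reversal potential matches a
#' measured dilution potential. The forward map is strictly monotone in the
#' ratio for asymmetric conditions, so the root is unique; measured
#' potentials outside the Nernst bounds (pure-Na and pure-Cl limits) have no
#' solution.
#'
#' @param vRev_mV Measured reversal potential, mV.
#' @param conditions Asymmetric [IonicConditions-class].
#' @param interval Log10 search interval for the ratio.
#' @param useActivities Use activities (default) or concentrations.
#' @return The permeability ratio PNa/PCl.
#' @examples
#' cond <- naclConditions(13.5, 135)
#' v <- ghkVrev(cond, pNaPCl = 9.5)
#' invertGhkDilution(v, cond)  # 9.5
#' @export
invertGhkDilution <- function(vRev_mV, conditions, interval = c(-8, 8),
                              useActivities = TRUE) {
  f <- function(lp) ghkVrev(conditions, 10^lp, useActivities = useActivities) - vRev_mV
  lo <- f(interval[1]); hi <- f(interval[2])
  if (!is.finite(lo) || !is.finite(hi) || lo * hi > 0)
    stop("reversal potential outside the Nernst bounds: no solution")
  r <- stats::uniroot(f, interval, tol = 1e-12)
  10^r$root
}

#' Relative permeability of a substituted cation from a biionic potential
#'
#' Solves the GHK equation for the permeability of the test cation (which
#' replaces basolateral Na) relative to Na, given the measured biionic
#' reversal potential and a known Na/Cl permeability ratio. The solution is
#' closed-form since the GHK exponential is linear in the unknown
#' permeability.
#'
#' @param vRev_mV Measured biionic reversal potential, mV.
#' @param conditions [IonicConditions-class] with the basolateral cation
#'   substituted (see [biionicConditions()]).
#' @param pNaPCl Known Na/Cl permeability ratio.
#' @param useActivities Use activities (default) or concentrations.
#' @return PX/PNa (dimensionless, > 0).
#' @examples
#' cond <- biionicConditions("MA")
#' biionicPxOverPna(0, cond, pNaPCl = 9.5)  # near 1 when Vrev ~ 0
#' @export
biionicPxOverPna <- function(vRev_mV, conditions, pNaPCl,
                             useActivities = TRUE) {
  stopifnot(is(conditions, "IonicConditions"), pNaPCl > 0)
  api <- conditions@apical; baso <- conditions@basolateral
  xIon <- setdiff(unique(c(api$ion, baso$ion)), c("Na", "Cl"))
  if (length(xIon) != 1L) stop("conditions must contain one substituted cation")
  u <- exp(vRev_mV / thermalVoltage(conditions@temperature))
  aNaA <- .ionActivity(api, "Na", useActivities)
  aNaB <- .ionActivity(baso, "Na", useActivities)
  aClA <- .ionActivity(api, "Cl", useActivities)
  aClB <- .ionActivity(baso, "Cl", useActivities)
  aXA <- .ionActivity(api, xIon, useActivities)
  aXB <- .ionActivity(baso, xIon, useActivities)
  den <- aXB - u * aXA
  if (den == 0) stop("degenerate substitution conditions")
  pX <- (u * (pNaPCl * aNaA + aClB) - pNaPCl * aNaB - aClA) / den
  if (pX < 0) stop("no positive-permeability solution for this potential")
  pX / pNaPCl
}

#' Absolute Na+ permeability by the Kimizuka-Koketsu method
#'
#' Converts transepithelial conductance and the Na/Cl permeability ratio to
#' an absolute Na+ permeability:
#' \deqn{P_{Na} = \frac{RT}{F^2}\, G\, \frac{p}{1+p}\, \frac{1}{a_{Na}}}
#' with \eqn{G = 1/TER} in S/cm^2, \eqn{p = P_{Na}/P_{Cl}} the transference
#' fraction ratio, and \eqn{a_{Na}} the bulk Na activity in mol/cm^3.
#' Linear in conductance; tends to \eqn{(RT/F^2) G / a_{Na}} as
#' \eqn{p \to \infty}.
#'
#' @param ter_ohm_cm2 Transepithelial resistance, Ohm.cm^2 (> 0).
#' @param pNaPCl Na/Cl permeability ratio.
#' @param conditions [IonicConditions-class]; the basolateral Na activity
#'   and the temperature are taken from it.
#' @return Absolute Na+ permeability, cm/s.
#' @examples
#' kimizukaKoketsuPNa(100, 9.5, naclConditions())
#' @export
kimizukaKoketsuPNa <- function(ter_ohm_cm2, pNaPCl, conditions = naclConditions()) {
  if (ter_ohm_cm2 <= 0) stop("TER must be > 0")
  aNa_mM <- .ionActivity(conditions@basolateral, "Na")
  if (aNa_mM <= 0) stop("zero Na activity")
  aNa_mol_cm3 <- aNa_mM * 1e-6          # mM = 1e-6 mol/cm^3
  G <- 1 / ter_ohm_cm2                  # S/cm^2
  RT_F2 <- .GAS_CONSTANT * conditions@temperature / .FARADAY^2
  RT_F2 * G * (pNaPCl / (1 + pNaPCl)) / aNa_mol_cm3
}
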