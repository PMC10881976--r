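# Inorganic-carbon speciation: the carbonate system behind the observation
# that near-neutral cytosolic inorganic carbon is mostly bicarbonate.

#' Carbonate-system parameters
#'
#' Apparent equilibrium constants for the diprotic carbonate system
#' (CO2(aq) + H2O <-> HCO3- + H+, pKa1; HCO3- <-> CO3^2- + H+, pKa2),
#' Henry solubility and CO2 partial pressure. Defaults are apparent
#' constants near 20 degrees C with present-day atmospheric pCO2; activity
#' corrections are out of scope, so constants are "apparent" by
#' construction.
#'
#' @param ph Solution pH.
#' @param temperature Temperature, degrees C (annotation only; constants are
#'   not regressed on it).
#' @param pka1,pka2 Apparent pKa values (pka1 < pka2).
#' @param kh Henry solubility of CO2, mol/(L atm).
#' @param pco2 CO2 partial pressure, atm.
#' @return A `carbonate_params` list.
#' @export
carbonate_params <- function(ph = 7.4, temperature = 20, pka1 = 6.06,
                             pka2 = 10.33, kh = 0.039, pco2 = 4.0e-4) {
  if (pka1 >= pka2) abort("pka1 must be < pka2")
  if (kh <= 0 || pco2 < 0) abort("kh must be > 0 and pco2 >= 0")
  structure(list(ph = ph, temperature = temperature, pka1 = pka1,
                 pka2 = pka2, kh = kh, pco2 = pco2),
            class = "carbonate_params")
}

#' Equilibrium fractions of dissolved inorganic carbon species
#'
#' Standard diprotic speciation: at `ph = pka1` the CO2(aq) and HCO3-
#' fractions are equal; the HCO3-/CO2 ratio rises tenfold per pH unit.
#'
#' @param ph pH value(s); vectorised.
#' @param pka1,pka2 Apparent pKa values.
#' @return Tibble with columns `ph`, `f_co2`, `f_hco3`, `f_co3` (fractions
#'   sum to 1).
#' @examples
#' species_fractions(7.4)
#' @export
species_fractions <- function(ph, pka1 = 6.06, pka2 = 10.33) {
  r1 <- 10^(ph - pka1)        # [HCO3-]/[CO2]
  r2 <- 10^(ph - pka2)        # [CO3--]/[HCO3-]
  denom <- 1 + r1 + r1 * r2
  tibble(ph = ph, f_co2 = 1 / denom, f_hco3 = r1 / denom,
         f_co3 = r1 * r2 / denom)
}

#' Dissolved CO2 concentration in equilibrium with a gas phase
#'
#' Henry's law: `[CO2(aq)] = kh * pCO2`.
#'
#' @param pco2 CO2 partial pressure, atm.
#' @param kh Henry solubility, mol/(L atm).
#' @return Concentration, mM.
#' @export
dissolved_co2 <- function(pco2, kh = 0.039) {
  if (any(pco2 < 0) || any(kh < 0)) abort("inputs must be >= 0")
  1000 * kh * pco2
}

#' Bicarbonate concentration in equilibrium with dissolved CO2
#'
#' Henderson-Hasselbalch: `[HCO3-] = [CO2] * 10^(ph - pka1)`.
#'
#' @param co2_mM Dissolved CO2, mM.
#' @param ph Solution pH.
#' @param pka1 Apparent first pKa.
#' @return Bicarbonate concentration, mM.
#' @examples
#' bicarbonate_from_co2(0.012, 7.4, 6.064) # ~0.26 mM
#' @export
bicarbonate_from_co2 <- function(co2_mM, ph, pka1 = 6.06) {
  if (any(co2_mM < 0)) abort("co2_mM must be >= 0")
  co2_mM * 10^(ph - pka1)
}

#' Full carbonate speciation state
#'
#' Either distributes a given total dissolved inorganic carbon (DIC) over
#' the three species, or builds the state from gas-phase equilibrium
#' (Henry's law for CO2(aq), then the two acid-base equilibria).
#'
#' @param params A [carbonate_params()].
#' @param dic Total dissolved inorganic carbon, mM; if `NULL`, the state is
#'   computed from `params$pco2` instead.
#' @return Tibble of class `carbonate_state` with `co2`, `hco3`, `co3` (mM),
#'   their fractions, and `dic`.
#' @export
speciate <- function(params = carbonate_params(), dic = NULL) {
  fr <- species_fractions(params$ph, params$pka1, params$pka2)
  if (is.null(dic)) {
    co2 <- dissolved_co2(params$pco2, params$kh)
    hco3 <- bicarbonate_from_co2(co2, params$ph, params$pka1)
    co3 <- hco3 * 10^(params$ph - params$pka2)
    dic <- co2 + hco3 + co3
  } else {
    if (dic < 0) abort("dic must be >= 0")
    co2 <- dic * fr$f_co2
    hco3 <- dic * fr$f_hco3
    co3 <- dic * fr$f_co3
  }
  out <- tibble(ph = params$ph, co2 = co2, hco3 = hco3, co3 = co3,
                dic = dic, f_co2 = fr$f_co2, f_hco3 = fr$f_hco3,
                f_co3 = fr$f_co3)
  class(out) <- c("carbonate_state", class(out))
  out
}
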