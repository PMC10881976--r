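# Yield and unit arithmetic for fermentation endpoints.

#' Unit constants used throughout the yield arithmetic
#'
#' Molecular weights at two-decimal standard values; the biomass Cmol mass
#' is computed from the composition, never hard-coded.
#'
#' @param biomass_formula Cmol biomass composition.
#' @return List with `mw_3hp`, `mw_glucose`, `od_to_dcw_factor`,
#'   `biomass_formula`, `m_biomass` (g/Cmol).
#' @export
unit_constants <- function(biomass_formula = "CH1.8O0.5N0.2") {
  list(
    mw_3hp = 90.08,
    mw_glucose = 180.16,
    od_to_dcw_factor = 0.7,
    biomass_formula = biomass_formula,
    m_biomass = formula_weight(biomass_formula)
  )
}

#' Mass yield of product on substrate
#'
#' @param titre Product concentration, g/L.
#' @param substrate_consumed Substrate consumed, g/L (> 0).
#' @return Yield, g product / g substrate.
#' @examples
#' mass_yield(11.25, 20) # 0.5625
#' @export
mass_yield <- function(titre, substrate_consumed) {
  if (any(substrate_consumed <= 0)) abort("substrate_consumed must be > 0")
  if (any(titre < 0)) abort("titre must be >= 0")
  titre / substrate_consumed
}

#' Convert a molar yield to a mass yield
#'
#' @param y Yield, mol product / mol substrate.
#' @param mw_product,mw_substrate Molecular weights, g/mol (> 0).
#' @return Yield, g/g.
#' @export
molar_to_mass_yield <- function(y, mw_product, mw_substrate) {
  if (any(mw_product <= 0) || any(mw_substrate <= 0)) {
    abort("molecular weights must be > 0")
  }
  y * mw_product / mw_substrate
}

#' Convert a mass yield to a molar yield
#'
#' Inverse of [molar_to_mass_yield()].
#'
#' @inheritParams molar_to_mass_yield
#' @param y Yield, g product / g substrate.
#' @return Yield, mol/mol.
#' @export
mass_to_molar_yield <- function(y, mw_product, mw_substrate) {
  if (any(mw_product <= 0) || any(mw_substrate <= 0)) {
    abort("molecular weights must be > 0")
  }
  y * mw_substrate / mw_product
}

#' Percentage of a theoretical maximum yield
#'
#' A measured yield above the theoretical maximum triggers a warning, not an
#' error (measurement noise can place an observation marginally above).
#'
#' @param y Observed yield, g/g.
#' @param y_max Theoretical maximum yield, g/g (> 0).
#' @return Percentage (100 x y / y_max).
#' @export
percent_of_theoretical <- function(y, y_max) {
  if (any(y_max <= 0)) abort("y_max must be > 0")
  if (any(y > y_max)) warn("observed yield exceeds the theoretical maximum")
  100 * y / y_max
}

#' Percent improvement of a new value over an old one
#'
#' @param new,old Values on the same scale; `old` must be > 0.
#' @return Percentage (100 x (new - old) / old).
#' @examples
#' percent_improvement(0.83, 0.65) # 27.7 at 1 d.p.
#' @export
percent_improvement <- function(new, old) {
  if (any(old <= 0)) abort("old value must be > 0")
  100 * (new - old) / old
}

#' Estimate dry cell weight from OD600
#'
#' Uses the standard conversion DCW = 0.7 x OD600 (g/L).
#'
#' @param od600 Optical density at 600 nm (>= 0); vectorised.
#' @param factor Conversion factor, g/L per OD unit.
#' @return DCW, g/L.
#' @export
od_to_dcw <- function(od600, factor = 0.7) {
  if (any(od600 < 0, na.rm = TRUE)) abort("od600 must be >= 0")
  factor * od600
}
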