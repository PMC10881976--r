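# Model expansion: the malonyl-CoA reductase (MCR) route to 3-HP, and the
# bicarbonate availability constraints swept by the envelope analysis.

#' Graft the malonyl-CoA reductase 3-HP pathway onto a model
#'
#' Adds exactly three reactions: reduction of malonyl-CoA to malonate
#' semialdehyde (MSA; the MCR-C step), reduction of MSA to
#' 3-hydroxypropionate (the MCR-N step), and a secretion-only 3-HP exchange.
#' Both reduction steps consume one reduced cofactor; NADPH is the default
#' (MCR chemistry), NADH selectable. The two new species (MSA, 3-HP) carry
#' full formulas and the added reactions are elementally balanced. The
#' `product_exchange` role is set on the new exchange; the input model is
#' left unmodified.
#'
#' @param model A `metabolic_model` containing malonyl-CoA, CoA, the chosen
#'   cofactor pair and a proton species.
#' @param cofactor `"NADPH"` (default) or `"NADH"`.
#' @param species Named list mapping the required species roles to metabolite
#'   ids in `model`: `malonyl_coa`, `coa`, `h`, and the cofactor pair
#'   (`nadph`/`nadp` or `nadh`/`nad`). Defaults match the bundled core
#'   model; override for third-party models (e.g. Yeast8 cytosolic ids).
#' @param compartment Compartment for the two new species.
#' @param product_exchange_id Id for the new exchange reaction.
#' @return Edited copy of the model (+3 reactions, +2 metabolites).
#' @examples
#' m <- build_core_model() |> add_3hp_pathway()
#' @export
add_3hp_pathway <- function(model, cofactor = c("NADPH", "NADH"),
                            species = list(), compartment = "c",
                            product_exchange_id = "EX_3hp") {
  cofactor <- match.arg(cofactor)
  defaults <- list(malonyl_coa = "malcoa", coa = "coa", h = "h",
                   nadph = "nadph", nadp = "nadp",
                   nadh = "nadh", nad = "nad")
  sp <- utils::modifyList(defaults, species)
  red <- if (cofactor == "NADPH") sp$nadph else sp$nadh
  ox <- if (cofactor == "NADPH") sp$nadp else sp$nad
  if (any(c("msa", "hp3") %in% model$metabolites$id) ||
      product_exchange_id %in% model$reactions$id) {
    abort("3-HP pathway already present in model")
  }
  for (need in c(sp$malonyl_coa, sp$coa, sp$h, red, ox)) {
    if (!need %in% model$metabolites$id) {
      abort(paste0("model lacks required species: '", need, "'"))
    }
  }
  mets <- dplyr::bind_rows(
    model$metabolites,
    metabolite("msa", name = "malonate semialdehyde", formula = "C3H4O3",
               charge = 0L, compartment = compartment),
    metabolite("hp3", name = "3-hydroxypropionate", formula = "C3H6O3",
               charge = 0L, compartment = compartment)
  )
  s_mcrc <- stats::setNames(
    c(-1, -1, -1, 1, 1, 1),
    c(sp$malonyl_coa, red, sp$h, "msa", sp$coa, ox)
  )
  s_mcrn <- stats::setNames(
    c(-1, -1, -1, 1, 1),
    c("msa", red, sp$h, "hp3", ox)
  )
  rxns <- dplyr::bind_rows(
    model$reactions,
    reaction("MCRC", s_mcrc,
             paste0("malonyl-CoA reduction to MSA (", cofactor, ")"),
             0, 1000),
    reaction("MCRN", s_mcrn,
             paste0("MSA reduction to 3-HP (", cofactor, ")"), 0, 1000),
    reaction(product_exchange_id, c(hp3 = -1), "3-HP exchange", 0, 1000,
             is_exchange = TRUE)
  )
  roles <- model$roles
  roles$product_exchange <- product_exchange_id
  metabolic_model(mets, rxns, roles = roles,
                  provenance = paste0(model$provenance,
                                      " + 3-HP pathway (", cofactor, ")"))
}

#' Cap bicarbonate formation relative to glucose uptake
#'
#' Sets the upper bound of the `bicarbonate_formation` reaction (the
#' carbonic-anhydrase-type CO2 -> HCO3- conversion) to
#' `ratio * |glucose_uptake|`, emulating a limited native supply of
#' bicarbonate from metabolic CO2. `ratio = Inf` restores an effectively
#' unbounded formation rate.
#'
#' @param model A `metabolic_model` with the `bicarbonate_formation` role.
#' @param ratio Dimensionless cap, >= 0, or `Inf`.
#' @param glucose_uptake Glucose uptake rate the cap is normalised to
#'   (mmol/gDCW/h; magnitude used).
#' @return Edited copy of the model.
#' @export
cap_bicarbonate_formation <- function(model, ratio, glucose_uptake = 1) {
  if (is.na(ratio) || ratio < 0) abort("ratio must be >= 0 (or Inf)")
  rid <- role_reaction(model, "bicarbonate_formation")
  i <- match(rid, model$reactions$id)
  ub <- if (is.infinite(ratio)) .FLUX_BIG else ratio * abs(glucose_uptake)
  model$reactions$upper_bound[i] <- ub
  model$reactions$lower_bound[i] <- min(model$reactions$lower_bound[i], ub)
  model$provenance <- paste0(model$provenance, sprintf(
    " | HCO3- formation cap %s x glucose", format(ratio)))
  model
}

#' Allow bicarbonate uptake from the medium
#'
#' Opens the `bicarbonate_exchange` lower bound to
#' `-ratio * |glucose_uptake|`, emulating supplementation of the medium with
#' bicarbonate (transporter-mediated influx). `ratio = 1` is the
#' one-to-one bicarbonate:glucose supplementation boundary.
#'
#' @inheritParams cap_bicarbonate_formation
#' @param ratio Maximal uptake relative to glucose, >= 0, or `Inf`.
#' @return Edited copy of the model.
#' @export
enable_bicarbonate_uptake <- function(model, ratio, glucose_uptake = 1) {
  if (is.na(ratio) || ratio < 0) abort("ratio must be >= 0 (or Inf)")
  rid <- role_reaction(model, "bicarbonate_exchange")
  i <- match(rid, model$reactions$id)
  lbnd <- if (is.infinite(ratio)) -.FLUX_BIG else -ratio * abs(glucose_uptake)
  model$reactions$lower_bound[i] <- lbnd
  model$reactions$upper_bound[i] <- max(model$reactions$upper_bound[i], lbnd)
  model$provenance <- paste0(model$provenance, sprintf(
    " | HCO3- uptake allowance %s x glucose", format(ratio)))
  model
}
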