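# Production envelopes: min/max product secretion across a growth grid for
# each bicarbonate availability setting, with mass-yield coordinates.

#' Specification of a production-envelope sweep
#'
#' @param glucose_uptake Glucose uptake rate fixed throughout, mmol/gDCW/h.
#' @param n_growth_points Number of points on the linear growth-fraction
#'   grid over `[0, 1]` (>= 2).
#' @param bicarbonate_ratios Bicarbonate availability ratios relative to
#'   glucose uptake; `Inf` is the unbounded setting.
#' @param mode `"formation_cap"` (native supply: cap on CO2 -> HCO3-
#'   conversion) or `"uptake_allowance"` (external supplementation); one
#'   value, or one per ratio.
#' @param product Product exchange reaction id; defaults to the model's
#'   `product_exchange` role at sweep time.
#' @return An `envelope_spec` list.
#' @export
envelope_spec <- function(glucose_uptake = 1, n_growth_points = 21,
                          bicarbonate_ratios = c(0, 0.25, 0.5, 1, Inf),
                          mode = "formation_cap", product = NULL) {
  if (n_growth_points < 2) abort("n_growth_points must be >= 2")
  if (any(bicarbonate_ratios < 0)) abort("bicarbonate ratios must be >= 0")
  mode <- match.arg(mode, c("formation_cap", "uptake_allowance"),
                    several.ok = TRUE)
  mode <- rep_len(mode, length(bicarbonate_ratios))
  structure(list(glucose_uptake = glucose_uptake,
                 n_growth_points = as.integer(n_growth_points),
                 bicarbonate_ratios = bicarbonate_ratios,
                 mode = mode, product = product),
            class = "envelope_spec")
}

# molecular weight of the single species an exchange reaction touches
exchange_species_mw <- function(model, rxn_id) {
  i <- match(rxn_id, model$reactions$id)
  if (is.na(i)) abort(paste0("no such reaction: '", rxn_id, "'"))
  sp <- names(model$reactions$stoichiometry[[i]])[1]
  f <- model$metabolites$formula[[match(sp, model$metabolites$id)]]
  if (is.null(f)) abort(paste0("species '", sp, "' has no formula"))
  formula_weight(f)
}

apply_bicarbonate_mode <- function(model, ratio, mode, glucose_uptake) {
  if (mode == "formation_cap") {
    if (!is.null(model$roles$bicarbonate_formation)) {
      return(cap_bicarbonate_formation(model, ratio, glucose_uptake))
    }
    # a missing formation reaction is only compatible with "no cap"
    if (is.infinite(ratio)) return(model)
    abort("finite formation cap requires the 'bicarbonate_formation' role")
  }
  if (mode == "uptake_allowance") {
    if (!is.null(model$roles$bicarbonate_exchange)) {
      return(enable_bicarbonate_uptake(model, ratio, glucose_uptake))
    }
    if (ratio == 0) return(model)   # closed exchange needs no role
    abort("uptake allowance requires the 'bicarbonate_exchange' role")
  }
  abort(paste0("unknown bicarbonate mode: ", mode))
}

#' Compute the production envelope of a model
#'
#' For each bicarbonate ratio: applies the ratio (as a formation cap or an
#' uptake allowance), fixes glucose uptake, finds the maximal growth rate,
#' and then minimises and maximises product secretion at each point of a
#' linear growth-fraction grid spanning `[0, mu_max]`. Yields are reported in
#' g/g using the molecular weights implied by the species formulas; the
#' biomass yield converts the growth rate through the gram-scaled biomass
#' drain (flux 1 = 1 g biomass/gDCW/h).
#'
#' Grid points that come back infeasible (a numerical edge near `mu_max`)
#' are retried once with the growth rate relaxed by 1e-9 and otherwise
#' marked `feasible = FALSE`, never dropped.
#'
#' @param model A `metabolic_model` with `glucose_exchange`, `biomass` and
#'   `product_exchange` (or `spec$product`) roles set.
#' @param spec An [envelope_spec()].
#' @return A tibble of class `envelope_grid` with columns `ratio`, `mode`,
#'   `mu`, `growth_fraction`, `product_min`, `product_max`, `yield_product`,
#'   `yield_biomass`, `feasible`, plus attributes `spec` and `mu_max` (one
#'   per ratio).
#' @examples
#' m <- build_core_model() |> add_3hp_pathway()
#' env <- compute_envelope(m, envelope_spec(bicarbonate_ratios = c(0, Inf),
#'                                          n_growth_points = 5))
#' @export
compute_envelope <- function(model, spec = envelope_spec()) {
  product <- spec$product %||% model$roles$product_exchange
  if (is.null(product)) abort("no product exchange role set")
  glc_ex <- role_reaction(model, "glucose_exchange")
  bio <- role_reaction(model, "biomass")
  mw_glc <- exchange_species_mw(model, glc_ex)
  mw_prod <- exchange_species_mw(model, product)
  uptake <- abs(spec$glucose_uptake)

  rows <- list()
  mu_maxes <- numeric(length(spec$bicarbonate_ratios))
  for (k in seq_along(spec$bicarbonate_ratios)) {
    ratio <- spec$bicarbonate_ratios[k]
    mode <- spec$mode[k]
    m <- apply_bicarbonate_mode(model, ratio, mode, uptake)
    m <- fix_flux(m, glc_ex, -uptake)
    gsol <- solve_fba(m, bio, "max")
    if (gsol$status != "optimal") {
      abort(paste0("model infeasible with glucose fixed (ratio ", ratio,
                   "): broken model or roles"))
    }
    mu_max <- gsol$objective_value
    mu_maxes[k] <- mu_max
    fracs <- seq(0, 1, length.out = spec$n_growth_points)
    for (f in fracs) {
      mu <- f * mu_max
      mf <- fix_flux(m, bio, mu)
      lo <- solve_fba(mf, product, "min")
      hi <- solve_fba(mf, product, "max")
      if (lo$status != "optimal" || hi$status != "optimal") {
        mf <- set_bounds(m, bio, max(mu - 1e-9, 0), mu)
        lo <- solve_fba(mf, product, "min")
        hi <- solve_fba(mf, product, "max")
      }
      ok <- lo$status == "optimal" && hi$status == "optimal"
      pmin_ <- if (ok) lo$objective_value else NA_real_
      pmax_ <- if (ok) hi$objective_value else NA_real_
      rows[[length(rows) + 1L]] <- tibble(
        ratio = ratio, mode = mode, mu = mu, growth_fraction = f,
        product_min = pmin_, product_max = pmax_,
        yield_product = pmax_ * mw_prod / (uptake * mw_glc),
        yield_biomass = mu * 1000 / (uptake * mw_glc),
        feasible = ok
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "spec") <- spec
  attr(out, "mu_max") <- stats::setNames(mu_maxes,
                                         format(spec$bicarbonate_ratios))
  attr(out, "mw") <- c(product = mw_prod, glucose = mw_glc)
  class(out) <- c("envelope_grid", class(out))
  out
}

#' Maximum theoretical product yield at zero growth
#'
#' Fixes glucose uptake and growth at zero, maximises product secretion and
#' reports the yield on glucose in both molar and mass units.
#'
#' @param model A `metabolic_model` with glucose/product roles set (apply
#'   bicarbonate settings beforehand).
#' @param glucose_uptake Glucose uptake rate, mmol/gDCW/h.
#' @return One-row tibble: `mol_per_mol`, `g_per_g`, `product_flux`,
#'   `status`.
#' @export
max_theoretical_yield <- function(model, glucose_uptake = 1) {
  glc_ex <- role_reaction(model, "glucose_exchange")
  product <- role_reaction(model, "product_exchange")
  m <- fix_flux(model, glc_ex, -abs(glucose_uptake))
  if (!is.null(model$roles$biomass)) m <- fix_flux(m, model$roles$biomass, 0)
  sol <- solve_fba(m, product, "max")
  if (sol$status != "optimal") {
    return(tibble(mol_per_mol = NA_real_, g_per_g = NA_real_,
                  product_flux = NA_real_, status = sol$status))
  }
  molar <- sol$objective_value / abs(glucose_uptake)
  tibble(
    mol_per_mol = molar,
    g_per_g = molar_to_mass_yield(molar,
                                  exchange_species_mw(model, product),
                                  exchange_species_mw(model, glc_ex)),
    product_flux = sol$objective_value,
    status = "optimal"
  )
}

#' Bicarbonate supply ratio at the zero-growth product optimum
#'
#' Fixes glucose uptake and growth at zero, takes the parsimonious product
#' optimum, and reports total bicarbonate supply (formation flux plus
#' uptake through the bicarbonate exchange) relative to glucose uptake.
#' The variability (FVA) range of the combined supply flux across alternate
#' optima is reported alongside.
#'
#' @inheritParams max_theoretical_yield
#' @return One-row tibble: `ratio`, `ratio_min`, `ratio_max`,
#'   `formation_flux`, `uptake_flux`, `product_flux`.
#' @export
bicarbonate_ratio_at_optimum <- function(model, glucose_uptake = 1) {
  glc_ex <- role_reaction(model, "glucose_exchange")
  product <- role_reaction(model, "product_exchange")
  form <- role_reaction(model, "bicarbonate_formation")
  bex <- role_reaction(model, "bicarbonate_exchange")
  uptake <- abs(glucose_uptake)
  m <- fix_flux(model, glc_ex, -uptake)
  if (!is.null(model$roles$biomass)) m <- fix_flux(m, model$roles$biomass, 0)
  psol <- parsimonious_refine(m, product, "max")
  if (psol$status != "optimal") {
    abort(paste0("product optimum not attainable: status ", psol$status))
  }
  v_form <- max(psol$fluxes[[form]], 0)
  v_up <- max(-psol$fluxes[[bex]], 0)
  # FVA of the combined supply v_form - v_exchange at the fixed optimum
  fx <- fix_at_optimum(m, product, "max")
  S <- stoichiometric_matrix(fx$model)
  b <- model_bounds(fx$model)
  cost <- as.numeric(fx$model$reactions$id == form) -
    as.numeric(fx$model$reactions$id == bex)
  lo <- lp_flux(S, cost, b$lb, b$ub, "min")
  hi <- lp_flux(S, cost, b$lb, b$ub, "max")
  tibble(
    ratio = (v_form + v_up) / uptake,
    ratio_min = lo$value / uptake,
    ratio_max = hi$value / uptake,
    formation_flux = v_form, uptake_flux = v_up,
    product_flux = psol$objective_value
  )
}

#' Map fermentation endpoints onto the envelope plane and classify them
#'
#' Converts each strain endpoint (titre, glucose consumed, biomass as DCW or
#' OD600) to `(yield_biomass, yield_product)` in g/g and classifies it
#' against each ratio's upper envelope: `inside`, `on` (within `tol` g/g) or
#' `outside`. DCW is imputed as 0.7 x OD600 when absent.
#'
#' @param strains Data frame with columns `strain`, `titre` (g/L), `glucose`
#'   (g/L consumed) and `dcw` (g/L) and/or `od600`.
#' @param grid An `envelope_grid` from [compute_envelope()].
#' @param tol Classification tolerance, g/g.
#' @return Tibble: one row per strain x ratio with `yield_product`,
#'   `yield_biomass`, `envelope_yield` (upper envelope at the strain's
#'   biomass yield; 0 beyond the growth range) and `status`.
#' @export
overlay_strains <- function(strains, grid, tol = 1e-3) {
  strains <- as_tibble(strains)
  if (!all(c("strain", "titre", "glucose") %in% names(strains))) {
    abort("strains must have columns strain, titre, glucose")
  }
  bad <- which(!(strains$glucose > 0))
  if (length(bad)) {
    abort(paste0("glucose consumed must be > 0 (rows: ",
                 paste(bad, collapse = ", "), ")"))
  }
  dcw <- if ("dcw" %in% names(strains)) strains$dcw else
    rep(NA_real_, nrow(strains))
  if ("od600" %in% names(strains)) {
    dcw <- ifelse(is.na(dcw), od_to_dcw(strains$od600), dcw)
  }
  yp <- strains$titre / strains$glucose
  yb <- dcw / strains$glucose
  ratios <- unique(grid$ratio)
  out <- list()
  for (rt in ratios) {
    g <- grid[grid$ratio == rt & grid$feasible, ]
    env_at <- function(x) {
      if (all(is.na(g$yield_product))) return(rep(NA_real_, length(x)))
      y <- stats::approx(g$yield_biomass, g$yield_product, xout = x,
                         ties = max)$y
      ifelse(is.na(y) & x > max(g$yield_biomass), 0, y)
    }
    ey <- env_at(yb)
    status <- dplyr::case_when(
      is.na(ey) ~ NA_character_,
      abs(yp - ey) <= tol ~ "on",
      yp < ey ~ "inside",
      TRUE ~ "outside"
    )
    out[[length(out) + 1L]] <- tibble(
      strain = strains$strain, ratio = rt,
      yield_product = yp, yield_biomass = yb,
      envelope_yield = ey, status = status
    )
  }
  res <- dplyr::bind_rows(out)
  top <- max(ratios)
  n_out <- sum(res$status[res$ratio == top] == "outside", na.rm = TRUE)
  if (n_out > 0) {
    warn(paste0(n_out, " strain(s) lie outside the most permissive (ratio ",
                format(top), ") envelope"))
  }
  res
}

#' One-row summary of an envelope grid
#'
#' @param x An `envelope_grid`.
#' @param ... Unused.
#' @export
glance.envelope_grid <- function(x, ...) {
  mu_max <- attr(x, "mu_max")
  x |>
    dplyr::group_by(.data$ratio, .data$mode) |>
    dplyr::summarise(
      mu_max = max(.data$mu),
      yield_at_zero_growth = .data$yield_product[which.min(.data$mu)],
      max_yield = max(.data$yield_product, na.rm = TRUE),
      .groups = "drop"
    )
}
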