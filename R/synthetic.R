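# Curated yeast central-carbon core model and synthetic fixtures.
#
# The core model is a hand-balanced ~30-reaction lumped network covering the
# routes the envelope analysis cares about: glycolysis, oxidative pentose
# phosphate pathway with a non-oxidative return, the phosphoketolase (PK)
# bypass to cytosolic acetyl-CoA, the PDH-bypass (Pdc/Ald/Acs), a lumped
# PDH+TCA oxidation, oxidative phosphorylation with a parameterisable P/O
# ratio, carbonic anhydrase CO2 <-> HCO3-, Acc1 carboxylation, pyruvate
# carboxylase, a malate-dehydrogenase/malic-enzyme transhydrogenation loop,
# ATP dissipation and a biomass pseudo-reaction of declared Cmol
# composition. Every internal reaction is elementally balanced (charged
# BiGG-style species formulas, with H+ and H2O free to close balances).
# It is a curated fixture, not a reduction of the Yeast8 genome-scale model,
# and is not claimed to reproduce Yeast8-specific yield values.

#' Configuration for the bundled yeast central-carbon core model
#'
#' @param po_ratio ATP produced per NADH (and per FADH2) oxidised in the
#'   respiratory chain; around 1 in \emph{S. cerevisiae}.
#' @param include_pk Include the phosphoketolase bypass (X5P -> acetyl
#'   phosphate + GAP; acetyl phosphate -> acetyl-CoA)?
#' @param ngam Non-growth-associated maintenance, mmol ATP/gDCW/h (lower
#'   bound on the ATP-dissipation reaction).
#' @param gam Growth-associated maintenance, mmol ATP/gDCW (embedded in the
#'   biomass reaction).
#' @param biomass_formula Cmol biomass composition.
#' @param ethanol_branch Include fermentative ethanol formation?
#' @return A `core_model_config` list.
#' @export
core_model_config <- function(po_ratio = 1.0, include_pk = TRUE, ngam = 0,
                              gam = 30, biomass_formula = "CH1.8O0.5N0.2",
                              ethanol_branch = TRUE) {
  if (po_ratio <= 0) abort("po_ratio must be > 0")
  if (gam < 0) abort("gam must be >= 0")
  if (ngam < 0) abort("ngam must be >= 0")
  structure(list(po_ratio = po_ratio, include_pk = include_pk, ngam = ngam,
                 gam = gam, biomass_formula = biomass_formula,
                 ethanol_branch = ethanol_branch),
            class = "core_model_config")
}

# Species table for the core model (BiGG-style charged formulas).
core_model_species <- function(biomass_formula) {
  defs <- list(
    glc    = list("D-glucose",            "C6H12O6",          0L),
    g6p    = list("glucose 6-phosphate",  "C6H11O9P",        -2L),
    gap    = list("glyceraldehyde 3-phosphate", "C3H5O6P",   -2L),
    ru5p   = list("ribulose 5-phosphate", "C5H9O8P",         -2L),
    x5p    = list("xylulose 5-phosphate", "C5H9O8P",         -2L),
    pyr    = list("pyruvate",             "C3H3O3",          -1L),
    acald  = list("acetaldehyde",         "C2H4O",            0L),
    etoh   = list("ethanol",              "C2H6O",            0L),
    ac     = list("acetate",              "C2H3O2",          -1L),
    acp    = list("acetyl phosphate",     "C2H3O5P",         -2L),
    coa    = list("coenzyme A",           "C21H32N7O16P3S",  -4L),
    accoa  = list("acetyl-CoA",           "C23H34N7O17P3S",  -4L),
    malcoa = list("malonyl-CoA",          "C24H34N7O19P3S",  -5L),
    oaa    = list("oxaloacetate",         "C4H2O5",          -2L),
    mal    = list("(S)-malate",           "C4H4O5",          -2L),
    co2    = list("carbon dioxide",       "CO2",              0L),
    hco3   = list("bicarbonate",          "CHO3",            -1L),
    o2     = list("oxygen",               "O2",               0L),
    h2o    = list("water",                "H2O",              0L),
    h      = list("proton",               "H",                1L),
    nh4    = list("ammonium",             "H4N",              1L),
    pi     = list("phosphate",            "HO4P",            -2L),
    atp    = list("ATP",                  "C10H12N5O13P3",   -4L),
    adp    = list("ADP",                  "C10H12N5O10P2",   -3L),
    nad    = list("NAD+",                 "C21H26N7O14P2",   -1L),
    nadh   = list("NADH",                 "C21H27N7O14P2",   -2L),
    nadp   = list("NADP+",                "C21H25N7O17P3",   -3L),
    nadph  = list("NADPH",                "C21H26N7O17P3",   -4L),
    fad    = list("FAD",                  "C27H31N9O15P2",   -2L),
    fadh2  = list("FADH2",                "C27H33N9O15P2",   -2L),
    biomass = list("biomass", biomass_formula, 0L)
  )
  dplyr::bind_rows(lapply(names(defs), function(id) {
    d <- defs[[id]]
    metabolite(id, name = d[[1]], formula = d[[2]], charge = d[[3]],
               compartment = "c")
  }))
}

# Biomass pseudo-reaction coefficients from the declared Cmol composition:
# carbon from glucose, nitrogen from ammonium, GAM mmol ATP hydrolysed, and
# H2O/H+ closing the elemental balance exactly. Flux 1 drains the precursors
# for 1 g biomass, so the reaction flux is the specific growth rate (1/h).
core_biomass_stoich <- function(biomass_formula, gam) {
  f <- parse_formula(biomass_formula)
  for (el in c("H", "O", "N")) if (is.na(f[el])) f[el] <- 0
  m_cmol <- formula_weight(f)                    # g per Cmol
  n <- 1000 / m_cmol                             # mmol Cmol per g biomass
  glc <- n / 6
  nh4 <- unname(f["N"]) * n
  h_in <- 12 * glc + 4 * nh4                     # H from C and N sources
  h_bio <- unname(f["H"]) * n
  o_in <- 6 * glc
  o_bio <- unname(f["O"]) * n
  h2o_out <- (h_in - h_bio) / 2                  # close H with water
  o_slack <- o_in - o_bio - h2o_out              # leftover O after closure
  # leftover O leaves as extra water, with compensating protons keeping H
  # exact; zero for the default CH1.8O0.5N0.2 composition
  h2o_out <- h2o_out + o_slack
  h_extra <- -2 * o_slack
  out <- c(glc = -glc, nh4 = -nh4, atp = -gam,
           h2o = h2o_out - gam, biomass = n,
           adp = gam, pi = gam, h = gam + h_extra)
  out[abs(out) > 1e-12]
}

#' Build the bundled yeast central-carbon core model
#'
#' See the package vignette for the network content and its rationale. The
#' returned model has all six semantic roles set (`glucose_exchange`,
#' `biomass`, `bicarbonate_formation`, `bicarbonate_exchange`,
#' `atp_dissipation`, and -- after [add_3hp_pathway()] -- `product_exchange`)
#' and passes [validate_elemental_balance()].
#'
#' @param config A [core_model_config()].
#' @return A `metabolic_model`.
#' @examples
#' m <- build_core_model()
#' validate_elemental_balance(m)$pass
#' @export
build_core_model <- function(config = core_model_config()) {
  stopifnot(inherits(config, "core_model_config"))
  p <- config$po_ratio
  mets <- core_model_species(config$biomass_formula)

  r <- list(
    # --- glycolysis (lumped) ---
    reaction("GLK", c(glc = -1, atp = -1, g6p = 1, adp = 1, h = 1),
             "hexokinase", 0, 1000),
    reaction("PFKA", c(g6p = -1, atp = -1, gap = 2, adp = 1, h = 1),
             "upper glycolysis (PFK/aldolase lump)", 0, 1000),
    reaction("GAPPYK",
             c(gap = -1, adp = -2, pi = -1, nad = -1,
               pyr = 1, atp = 2, nadh = 1, h2o = 1),
             "lower glycolysis (GAPDH..PYK lump)", -1000, 1000),
    # --- oxidative PPP + non-oxidative return ---
    reaction("G6PDH",
             c(g6p = -1, nadp = -2, h2o = -1,
               ru5p = 1, co2 = 1, nadph = 2, h = 2),
             "oxidative PPP (G6PDH/6PGDH lump)", 0, 1000),
    reaction("RPE", c(ru5p = -1, x5p = 1), "ribulose-5P epimerase",
             -1000, 1000),
    reaction("TKTL", c(x5p = -6, h2o = -1, g6p = 5, pi = 1),
             "non-oxidative PPP return (TKT/TAL lump)", -1000, 1000),
    # --- PDH bypass to cytosolic acetyl-CoA ---
    reaction("PDC", c(pyr = -1, h = -1, acald = 1, co2 = 1),
             "pyruvate decarboxylase", 0, 1000),
    reaction("ALD6", c(acald = -1, nadp = -1, h2o = -1,
                       ac = 1, nadph = 1, h = 2),
             "acetaldehyde dehydrogenase (NADP)", 0, 1000),
    reaction("ACS", c(ac = -1, atp = -2, coa = -1, h2o = -1,
                      accoa = 1, adp = 2, pi = 2, h = 1),
             "acetyl-CoA synthetase (AMP lumped as 2 ATP)", 0, 1000),
    # --- respiration ---
    reaction("TCA",
             c(pyr = -1, nad = -4, fad = -1, adp = -1, pi = -1, h2o = -2,
               co2 = 3, nadh = 4, fadh2 = 1, atp = 1, h = 2),
             "pyruvate oxidation (PDH + TCA lump)", 0, 1000),
    reaction("RESP_NADH",
             c(nadh = -1, h = -(1 + p), o2 = -0.5, adp = -p, pi = -p,
               nad = 1, atp = p, h2o = 1 + p),
             "NADH respiration (P/O-coupled)", 0, 1000),
    reaction("RESP_FADH2",
             c(fadh2 = -1, o2 = -0.5, adp = -p, pi = -p, h = -p,
               fad = 1, atp = p, h2o = 1 + p),
             "FADH2 respiration (P/O-coupled)", 0, 1000),
    # --- inorganic carbon ---
    reaction("CA", c(co2 = -1, h2o = -1, hco3 = 1, h = 1),
             "carbonic anhydrase (bicarbonate formation)", -1000, 1000),
    # --- carboxylations and NADPH loop ---
    reaction("ACC1", c(accoa = -1, hco3 = -1, atp = -1,
                       malcoa = 1, adp = 1, pi = 1),
             "acetyl-CoA carboxylase", 0, 1000),
    reaction("PYC", c(pyr = -1, hco3 = -1, atp = -1,
                      oaa = 1, adp = 1, pi = 1, h = 1),
             "pyruvate carboxylase", 0, 1000),
    reaction("MDH", c(oaa = -1, nadh = -1, h = -1, mal = 1, nad = 1),
             "malate dehydrogenase", -1000, 1000),
    reaction("ME", c(mal = -1, nadp = -1, pyr = 1, co2 = 1, nadph = 1),
             "malic enzyme (NADP)", 0, 1000),
    # --- maintenance and biomass ---
    reaction("ATPM", c(atp = -1, h2o = -1, adp = 1, pi = 1, h = 1),
             "ATP dissipation (maintenance)", config$ngam, 1000),
    reaction("BIOMASS", core_biomass_stoich(config$biomass_formula,
                                            config$gam),
             "biomass pseudo-reaction", 0, 1000)
  )
  if (config$include_pk) {
    r <- c(r, list(
      reaction("XPK", c(x5p = -1, pi = -1, acp = 1, gap = 1, h2o = 1),
               "phosphoketolase", 0, 1000),
      reaction("PTA", c(acp = -1, coa = -1, accoa = 1, pi = 1),
               "phosphotransacetylase", -1000, 1000)
    ))
  }
  if (config$ethanol_branch) {
    r <- c(r, list(
      reaction("ADH", c(acald = -1, nadh = -1, h = -1, etoh = 1, nad = 1),
               "alcohol dehydrogenase", -1000, 1000)
    ))
  }
  ex <- list(
    reaction("EX_glc", c(glc = -1), "D-glucose exchange", -10, 1000,
             is_exchange = TRUE),
    reaction("EX_o2", c(o2 = -1), "oxygen exchange", -1000, 1000,
             is_exchange = TRUE),
    reaction("EX_co2", c(co2 = -1), "CO2 exchange", 0, 1000,
             is_exchange = TRUE),
    reaction("EX_hco3", c(hco3 = -1), "bicarbonate exchange", 0, 1000,
             is_exchange = TRUE),
    reaction("EX_nh4", c(nh4 = -1), "ammonium exchange", -1000, 1000,
             is_exchange = TRUE),
    reaction("EX_h2o", c(h2o = -1), "water exchange", -1000, 1000,
             is_exchange = TRUE),
    reaction("EX_h", c(h = -1), "proton exchange", -1000, 1000,
             is_exchange = TRUE),
    reaction("EX_biomass", c(biomass = -1), "biomass sink", 0, 1000,
             is_exchange = TRUE)
  )
  if (config$ethanol_branch) {
    ex <- c(ex, list(reaction("EX_etoh", c(etoh = -1), "ethanol exchange",
                              0, 1000, is_exchange = TRUE)))
  }
  ex <- c(ex, list(reaction("EX_ac", c(ac = -1), "acetate exchange", 0, 1000,
                            is_exchange = TRUE)))

  # drop species that ended up unused (e.g. etoh/acp when branches disabled)
  rxns <- dplyr::bind_rows(c(r, ex))
  used <- unique(unlist(lapply(rxns$stoichiometry, names)))
  mets <- mets[mets$id %in% used, ]

  metabolic_model(
    mets, rxns,
    roles = list(glucose_exchange = "EX_glc", biomass = "BIOMASS",
                 bicarbonate_formation = "CA", bicarbonate_exchange = "EX_hco3",
                 atp_dissipation = "ATPM"),
    provenance = sprintf(
      "fluxenv core model (P/O=%g, PK=%s, GAM=%g, NGAM=%g, biomass %s)",
      config$po_ratio, config$include_pk, config$gam, config$ngam,
      config$biomass_formula)
  )
}

#' Toy linear-chain model (oracle fixture)
#'
#' `S_ext -> S -> P -> P_ext` with substrate uptake bounded at 1; the
#' maximal export of P is exactly 1.
#'
#' @return A `metabolic_model` (4 reactions).
#' @export
build_toy_linear_model <- function() {
  mets <- dplyr::bind_rows(
    metabolite("S", formula = "C1H2O1"),
    metabolite("P", formula = "C1H2O1")
  )
  rxns <- dplyr::bind_rows(
    reaction("EX_S", c(S = -1), "substrate exchange", -1, 0,
             is_exchange = TRUE),
    reaction("CONV", c(S = -1, P = 1), "isomerisation", 0, 1000),
    reaction("EX_P", c(P = -1), "product exchange", 0, 1000,
             is_exchange = TRUE)
  )
  metabolic_model(mets, rxns,
                  roles = list(glucose_exchange = "EX_S",
                               product_exchange = "EX_P"),
                  provenance = "fluxenv toy linear chain")
}

#' Toy branch model with a closed-form production envelope (oracle fixture)
#'
#' Substrate S (1 Cmol, CH2O) splits 1:1 into product P (CH2O) or biomass B
#' (CH2O). The biomass drain is scaled so its flux is in 1/h (g biomass per
#' gDCW per h), as in the core model. The envelope in yield space is the
#' straight line from (Yb_max, 0) to (0, Yp_max) given in closed form by
#' [analytic_envelope_toy()].
#'
#' @param uptake Substrate uptake bound, mmol/gDCW/h.
#' @return A `metabolic_model` (5 reactions).
#' @export
build_toy_branch_model <- function(uptake = 1) {
  mw <- formula_weight("C1H2O1")
  k <- 1000 / mw   # mmol S per gram biomass (1:1 Cmol incorporation)
  mets <- dplyr::bind_rows(
    metabolite("S", formula = "C1H2O1"),
    metabolite("P", formula = "C1H2O1"),
    metabolite("B", formula = "C1H2O1")
  )
  rxns <- dplyr::bind_rows(
    reaction("EX_S", c(S = -1), "substrate exchange", -uptake, 0,
             is_exchange = TRUE),
    reaction("RP", c(S = -1, P = 1), "product branch", 0, 1000),
    reaction("GROWTH", c(S = -k, B = k), "biomass branch", 0, 1000),
    reaction("EX_P", c(P = -1), "product exchange", 0, 1000,
             is_exchange = TRUE),
    reaction("EX_B", c(B = -1), "biomass sink", 0, 1000, is_exchange = TRUE)
  )
  metabolic_model(mets, rxns,
                  roles = list(glucose_exchange = "EX_S", biomass = "GROWTH",
                               product_exchange = "EX_P"),
                  provenance = "fluxenv toy branch model")
}

#' Closed-form envelope of the toy branch model
#'
#' For the 1:1 branch network the upper envelope is linear:
#' `yield_product(mu) = Yp_max * (1 - mu/mu_max)`, with
#' `mu_max = uptake * MW_S / 1000` and `Yp_max = 1` g/g.
#'
#' @param uptake Substrate uptake bound used when building the toy model.
#' @return List with `mu_max`, `yp_max`, `yb_max` and `yield_product`, a
#'   function of growth rate `mu`.
#' @export
analytic_envelope_toy <- function(uptake = 1) {
  mw <- formula_weight("C1H2O1")
  mu_max <- uptake * mw / 1000
  yp_max <- 1
  list(
    mu_max = mu_max, yp_max = yp_max, yb_max = 1,
    yield_product = function(mu) yp_max * (1 - mu / mu_max),
    product_flux = function(mu) uptake * (1 - mu / mu_max)
  )
}

#' Generate a synthetic strain endpoint table with known ground truth
#'
#' Emulates shake-flask fermentation endpoints: per strain, a 3-HP titre and
#' a dry-cell-weight measurement derived from true yields with multiplicative
#' Gaussian noise.
#'
#' @param truth Data frame (or tibble) with columns `yield_product` and
#'   `yield_biomass` (g/g truths), one row per strain; a list of two-element
#'   vectors is also accepted.
#' @param glucose Glucose consumed, g/L (shake-flask cultures here use
#'   20 g/L).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed; same seed, same table.
#' @return Tibble with columns `strain`, `titre`, `glucose`, `dcw`, `od600`
#'   and the ground-truth yields (`yield_product_true`,
#'   `yield_biomass_true`).
#' @export
generate_strain_table <- function(truth, glucose = 20, noise_cv = 0,
                                  seed = 1L) {
  if (!is.data.frame(truth)) {
    truth <- dplyr::bind_rows(lapply(truth, function(v) {
      tibble(yield_product = v[[1]], yield_biomass = v[[2]])
    }))
  }
  if (any(truth$yield_product < 0) || any(truth$yield_biomass < 0)) {
    abort("truth yields must be >= 0")
  }
  if (noise_cv < 0) abort("noise_cv must be >= 0")
  n <- nrow(truth)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  eps_t <- stats::rnorm(n, 0, noise_cv)
  eps_b <- stats::rnorm(n, 0, noise_cv)
  titre <- truth$yield_product * glucose * (1 + eps_t)
  dcw <- truth$yield_biomass * glucose * (1 + eps_b)
  if (any(titre < 0) || any(dcw < 0)) {
    warn("negative generated values clipped at 0")
    titre <- pmax(titre, 0); dcw <- pmax(dcw, 0)
  }
  tibble(
    strain = sprintf("SYN%03d", seq_len(n)),
    titre = titre, glucose = glucose, dcw = dcw,
    od600 = dcw / 0.7,
    yield_product_true = truth$yield_product,
    yield_biomass_true = truth$yield_biomass
  )
}

#' Published fermentation endpoints bundled with the package
#'
#' Shake-flask endpoint titres for the engineered 3-HP strain series (20 g/L
#' glucose); OD600 is included where printed.
#'
#' @return Tibble with columns `strain`, `titre`, `glucose`, `od600`.
#' @export
strain_endpoints <- function() {
  path <- system.file("extdata", "strain_endpoints.csv", package = "fluxenv",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE) |> as_tibble()
}
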