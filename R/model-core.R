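#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Standard atomic masses (g/mol) for the elements a stoichiometric model may
# use. Restricted set; extra elements must be declared via `extra_elements`.
.ATOMIC_MASS <- c(
  C = 12.011, H = 1.008, O = 15.999, N = 14.007, P = 30.974, S = 32.06
)

#' Parse a chemical formula string into an element-count vector
#'
#' Accepts Hill-style formulas with integer or fractional counts, e.g.
#' `"C6H12O6"` or the Cmol biomass composition `"CH1.8O0.5N0.2"`.
#'
#' @param x Formula string, or an already-named numeric vector (returned
#'   unchanged after validation).
#' @param extra_elements Character vector of element symbols allowed beyond
#'   C, H, O, N, P, S.
#' @return Named numeric vector of element counts.
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("CH1.8O0.5N0.2")
#' @export
parse_formula <- function(x, extra_elements = character()) {
  allowed <- c(names(.ATOMIC_MASS), extra_elements)
  if (is.numeric(x)) {
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      abort("numeric formula must be a named element->count vector")
    }
    bad <- setdiff(names(x), allowed)
    if (length(bad)) abort(paste0("formula uses undeclared element(s): ",
                                  paste(bad, collapse = ", ")))
    return(x[x != 0])
  }
  if (!is.character(x) || length(x) != 1L || !nzchar(x)) {
    abort("formula must be a single non-empty string or named numeric vector")
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", x)[[1]]
  parts <- regmatches(x, list(m))[[1]]
  if (!length(parts) || sum(attr(m, "match.length")) != nchar(x)) {
    abort(paste0("cannot parse formula: '", x, "'"))
  }
  el <- sub("^([A-Z][a-z]?).*$", "\\1", parts)
  ct <- sub("^[A-Z][a-z]?", "", parts)
  ct <- ifelse(ct == "", 1, as.numeric(ct))
  bad <- setdiff(el, allowed)
  if (length(bad)) abort(paste0("formula uses undeclared element(s): ",
                                paste(bad, collapse = ", ")))
  out <- tapply(ct, el, sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Molecular weight of a formula
#'
#' @inheritParams parse_formula
#' @param masses Named vector of atomic masses; defaults to standard values.
#' @return Mass in g/mol.
#' @examples
#' formula_weight("C3H6O3") # 3-HP, 90.08
#' @export
formula_weight <- function(x, masses = .ATOMIC_MASS) {
  f <- parse_formula(x, extra_elements = setdiff(names(masses), names(.ATOMIC_MASS)))
  missing <- setdiff(names(f), names(masses))
  if (length(missing)) abort(paste0("no atomic mass for: ",
                                    paste(missing, collapse = ", ")))
  sum(f * masses[names(f)])
}

#' Construct a metabolite record
#'
#' @param id Unique metabolite identifier.
#' @param name Human-readable name.
#' @param formula Elemental composition (string or named numeric vector), or
#'   `NULL` when unknown.
#' @param charge Integer formal charge.
#' @param compartment Compartment identifier (non-empty).
#' @return One-row tibble with a list-column `formula`.
#' @export
metabolite <- function(id, name = id, formula = NULL, charge = 0L,
                       compartment = "c") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!nzchar(compartment)) abort("compartment must be non-empty")
  f <- if (is.null(f_in <- formula)) NULL else parse_formula(formula)
  tibble(id = id, name = name, formula = list(f),
         charge = as.integer(charge), compartment = compartment)
}

#' Construct a reaction record
#'
#' Stoichiometric coefficients follow the usual constraint-based convention:
#' negative = consumed, positive = produced. For exchange reactions the
#' single coefficient is -1 so that negative flux is uptake and positive flux
#' is secretion.
#'
#' @param id Unique reaction identifier.
#' @param stoichiometry Named numeric vector, metabolite id -> coefficient.
#' @param name Human-readable name.
#' @param lower_bound,upper_bound Flux bounds in mmol/gDCW/h.
#' @param is_exchange Logical; exchange reactions touch exactly one
#'   metabolite.
#' @return One-row tibble with a list-column `stoichiometry`.
#' @export
reaction <- function(id, stoichiometry, name = id,
                     lower_bound = -1000, upper_bound = 1000,
                     is_exchange = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(stoichiometry) || is.null(names(stoichiometry)) ||
      !length(stoichiometry)) {
    abort(paste0("reaction '", id, "': stoichiometry must be a non-empty ",
                 "named numeric vector"))
  }
  if (lower_bound > upper_bound) {
    abort(paste0("reaction '", id, "': lower_bound > upper_bound"))
  }
  if (is_exchange && length(stoichiometry) != 1L) {
    abort(paste0("exchange reaction '", id, "' must touch exactly one ",
                 "metabolite"))
  }
  tibble(id = id, name = name, stoichiometry = list(stoichiometry),
         lower_bound = as.numeric(lower_bound),
         upper_bound = as.numeric(upper_bound),
         is_exchange = is_exchange)
}

#' Assemble a metabolic model
#'
#' @param metabolites Tibble of metabolite records (rows from
#'   [metabolite()]).
#' @param reactions Tibble of reaction records (rows from [reaction()]).
#' @param roles Named list mapping semantic roles (`glucose_exchange`,
#'   `biomass`, `product_exchange`, `bicarbonate_formation`,
#'   `bicarbonate_exchange`, `atp_dissipation`) to reaction ids. Unknown
#'   roles are allowed; unset roles are simply absent.
#' @param provenance Free-text source tag; model edits append to it.
#' @return Object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, roles = list(),
                            provenance = "") {
  model <- structure(
    list(metabolites = as_tibble(metabolites),
         reactions = as_tibble(reactions),
         roles = roles, provenance = provenance),
    class = "metabolic_model"
  )
  validate_model(model)
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", nrow(x$metabolites), " metabolites, ",
      nrow(x$reactions), " reactions\n", sep = "")
  if (length(x$roles)) {
    cat("roles: ", paste(names(x$roles), unlist(x$roles), sep = "=",
                         collapse = ", "), "\n", sep = "")
  }
  if (nzchar(x$provenance)) cat("provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

# Structural validation; called by every constructor and editing helper.
validate_model <- function(model) {
  mets <- model$metabolites
  rxns <- model$reactions
  if (anyDuplicated(mets$id)) abort("duplicate metabolite ids")
  if (anyDuplicated(rxns$id)) abort("duplicate reaction ids")
  if (any(!nzchar(mets$compartment))) abort("empty compartment")
  if (any(rxns$lower_bound > rxns$upper_bound)) {
    bad <- rxns$id[rxns$lower_bound > rxns$upper_bound]
    abort(paste0("lower_bound > upper_bound in: ", paste(bad, collapse = ", ")))
  }
  keys <- unique(unlist(lapply(rxns$stoichiometry, names)))
  unknown <- setdiff(keys, mets$id)
  if (length(unknown)) {
    abort(paste0("stoichiometry references unknown metabolite(s): ",
                 paste(unknown, collapse = ", ")))
  }
  n_touch <- vapply(rxns$stoichiometry, length, 1L)
  bad_ex <- rxns$id[rxns$is_exchange & n_touch != 1L]
  if (length(bad_ex)) {
    abort(paste0("exchange reactions must touch exactly one metabolite: ",
                 paste(bad_ex, collapse = ", ")))
  }
  role_ids <- unlist(model$roles)
  missing <- setdiff(role_ids, rxns$id)
  if (length(missing)) {
    abort(paste0("role refers to unknown reaction(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(names(model$roles))) abort("duplicate role names")
  invisible(model)
}

# Resolve a role to a reaction id, with a clear error naming the role.
role_reaction <- function(model, role) {
  id <- model$roles[[role]]
  if (is.null(id)) {
    abort(paste0("model has no '", role, "' role; set it in model$roles"))
  }
  id
}

#' Stoichiometric matrix S (metabolites x reactions)
#'
#' @param model A `metabolic_model`.
#' @return Sparse `dgCMatrix` with metabolite ids as rownames and reaction
#'   ids as colnames; entry (i, j) is the coefficient of metabolite i in
#'   reaction j.
#' @export
stoichiometric_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(rxns)) {
    s <- model$reactions$stoichiometry[[j]]
    ii <- c(ii, match(names(s), mets))
    jj <- c(jj, rep.int(j, length(s)))
    xx <- c(xx, unname(s))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(mets), length(rxns)),
                       dimnames = list(mets, rxns))
}

#' Check elemental balance of all internal reactions
#'
#' Internal (non-exchange) reactions are checked element by element from the
#' metabolite formulas. A metabolite lacking a formula inside an internal
#' reaction is reported, not thrown. Exchange reactions are boundary drains
#' and are exempt by construction.
#'
#' @param model A `metabolic_model`.
#' @param tol Absolute tolerance on each element count.
#' @return A `balance_report`: list with `imbalance` (tibble: reaction,
#'   element, imbalance), `unbalanced` (reaction ids), `missing_formula`
#'   (reaction ids with formula-less metabolites) and `pass` (TRUE iff
#'   `unbalanced` and `missing_formula` are empty).
#' @export
validate_elemental_balance <- function(model, tol = 1e-6) {
  mets <- model$metabolites
  fmap <- stats::setNames(mets$formula, mets$id)
  rows <- list()
  unbalanced <- character(0)
  missing_formula <- character(0)
  internal <- model$reactions[!model$reactions$is_exchange, ]
  for (j in seq_len(nrow(internal))) {
    s <- internal$stoichiometry[[j]]
    fs <- fmap[names(s)]
    if (any(vapply(fs, is.null, TRUE))) {
      missing_formula <- c(missing_formula, internal$id[j])
      next
    }
    els <- unique(unlist(lapply(fs, names)))
    bal <- stats::setNames(numeric(length(els)), els)
    for (k in seq_along(s)) {
      f <- fs[[k]]
      bal[names(f)] <- bal[names(f)] + s[[k]] * f
    }
    off <- bal[abs(bal) > tol]
    if (length(off)) {
      unbalanced <- c(unbalanced, internal$id[j])
      rows[[length(rows) + 1L]] <- tibble(
        reaction = internal$id[j], element = names(off),
        imbalance = unname(off)
      )
    }
  }
  structure(
    list(
      imbalance = if (length(rows)) dplyr::bind_rows(rows) else
        tibble(reaction = character(), element = character(),
               imbalance = numeric()),
      unbalanced = unbalanced,
      missing_formula = missing_formula,
      pass = !length(unbalanced) && !length(missing_formula)
    ),
    class = "balance_report"
  )
}

#' @export
print.balance_report <- function(x, ...) {
  cat("<balance_report> ", if (x$pass) "PASS" else "FAIL", "\n", sep = "")
  if (length(x$unbalanced)) {
    cat("unbalanced:", paste(x$unbalanced, collapse = ", "), "\n")
    print(x$imbalance)
  }
  if (length(x$missing_formula)) {
    cat("missing formulas in:", paste(x$missing_formula, collapse = ", "), "\n")
  }
  invisible(x)
}

# Carbon crossing the model boundary for a flux solution: sum over exchange
# reactions of (flux x carbon content). Exactly zero on a balanced model.
#' Net carbon flux across all exchange reactions of a solution
#'
#' On an elementally balanced model at steady state this is zero: carbon
#' entering via uptake equals carbon leaving via secretion (the biomass drain
#' counts through its sink exchange).
#'
#' @param model A `metabolic_model`.
#' @param solution A `flux_solution` from [solve_fba()].
#' @return Net carbon flux, mmol C/gDCW/h (positive = net export).
#' @export
carbon_exchange_balance <- function(model, solution) {
  ex <- model$reactions[model$reactions$is_exchange, ]
  total <- 0
  fmap <- stats::setNames(model$metabolites$formula, model$metabolites$id)
  for (j in seq_len(nrow(ex))) {
    s <- ex$stoichiometry[[j]]
    f <- fmap[[names(s)[1]]]
    cc <- if (is.null(f) || is.na(f["C"])) 0 else f[["C"]]
    # coefficient is -1 by convention: positive flux removes the metabolite
    total <- total + solution$fluxes[[ex$id[j]]] * (-s[[1]]) * cc
  }
  total
}
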