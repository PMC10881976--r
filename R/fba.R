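# Flux balance analysis: max/min c'v subject to S v = 0, lb <= v <= ub.
#
# LPs are solved with the package's bounded-variable revised simplex
# (R/simplex.R). Non-finite bounds are capped at `big` (the standard 1000
# mmol/gDCW/h convention), so every LP is bounded and the solver's status is
# either optimal or infeasible; an optimum pinned against the artificial cap
# is reported as "unbounded".

.FLUX_BIG <- 1000

# Solve max/min cost'v s.t. S v = 0, lb <= v <= ub. Returns list(status, v,
# value).
lp_flux <- function(S, cost, lb, ub, sense = c("max", "min"),
                    big = .FLUX_BIG) {
  sense <- match.arg(sense)
  lb <- pmax(lb, -big)
  ub <- pmin(ub, big)
  if (any(lb > ub)) {
    return(list(status = "infeasible", v = NULL, value = NA_real_))
  }
  S <- as.matrix(S)
  res <- simplex_box(S, rep(0, nrow(S)), cost, lb, ub, sense)
  if (res$status != "optimal") {
    return(list(status = res$status, v = NULL, value = NA_real_))
  }
  v <- res$x
  names(v) <- colnames(S)
  status <- "optimal"
  # optimum pressed against the artificial cap => unbounded direction
  hit <- which(cost != 0)
  if (length(hit) && any(abs(v[hit]) >= big - 1e-6) &&
      abs(res$value) >= big - 1e-6) {
    status <- "unbounded"
  }
  list(status = status, v = v, value = res$value)
}

# Extract lb/ub vectors from a model.
model_bounds <- function(model) {
  list(lb = model$reactions$lower_bound, ub = model$reactions$upper_bound)
}

new_flux_solution <- function(status, objective, sense, value, v, residual) {
  structure(
    list(status = status, objective = objective, sense = sense,
         objective_value = value, fluxes = v,
         steady_state_residual = residual),
    class = "flux_solution"
  )
}

#' Flux balance analysis
#'
#' Maximises (or minimises) the flux of one reaction subject to steady state
#' `S v = 0` and the model's flux bounds. Deterministic: the same model and
#' objective always return the same optimum value. Note that the flux
#' *vector* at the optimum is generally not unique; use
#' [parsimonious_refine()] for a canonical representative and
#' [flux_range_at_optimum()] for the range of any single flux among the
#' alternate optima.
#'
#' @param model A `metabolic_model`.
#' @param objective Reaction id to optimise; defaults to the model's
#'   `biomass` role.
#' @param sense `"max"` or `"min"`.
#' @return A `flux_solution` with fields `status` (`"optimal"`,
#'   `"infeasible"` or `"unbounded"`), `objective_value`, `fluxes` (named
#'   vector) and `steady_state_residual` (max |S v|).
#' @examples
#' m <- build_toy_linear_model()
#' solve_fba(m, objective = "EX_P")
#' @export
solve_fba <- function(model, objective = NULL, sense = c("max", "min")) {
  sense <- match.arg(sense)
  objective <- objective %||% model$roles$biomass
  if (is.null(objective)) abort("no objective given and no 'biomass' role set")
  if (!objective %in% model$reactions$id) {
    abort(paste0("objective reaction not in model: '", objective, "'"))
  }
  S <- stoichiometric_matrix(model)
  b <- model_bounds(model)
  cost <- as.numeric(model$reactions$id == objective)
  res <- lp_flux(S, cost, b$lb, b$ub, sense)
  if (res$status != "optimal") {
    return(new_flux_solution(res$status, objective, sense, NA_real_, NULL,
                             NA_real_))
  }
  residual <- max(abs(as.numeric(S %*% res$v)))
  new_flux_solution("optimal", objective, sense, res$value, res$v, residual)
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status: ", x$status, sep = "")
  if (x$status == "optimal") {
    cat(", ", x$sense, " ", x$objective, " = ",
        format(x$objective_value, digits = 8),
        " (residual ", format(x$steady_state_residual, digits = 3), ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Tidy a flux solution into a reaction/flux tibble
#'
#' @param x A `flux_solution`.
#' @param ... Unused.
#' @return Tibble with columns `reaction`, `flux`.
#' @importFrom generics tidy
#' @export
tidy.flux_solution <- function(x, ...) {
  if (x$status != "optimal") {
    return(tibble(reaction = character(), flux = numeric()))
  }
  tibble(reaction = names(x$fluxes), flux = unname(x$fluxes))
}

#' One-row summary of a flux solution
#'
#' @param x A `flux_solution`.
#' @param ... Unused.
#' @importFrom generics glance
#' @export
glance.flux_solution <- function(x, ...) {
  tibble(status = x$status, objective = x$objective, sense = x$sense,
         objective_value = x$objective_value,
         steady_state_residual = x$steady_state_residual)
}

#' Fix a reaction flux to a single value
#'
#' Sets both bounds to `value`. The input model is unmodified; an edited
#' copy is returned (all editing helpers in this package are pure).
#'
#' @param model A `metabolic_model`.
#' @param reaction_id Reaction to fix.
#' @param value Flux value (uptake is negative for exchange reactions).
#' @return Edited copy of the model.
#' @examples
#' m <- build_core_model()
#' m <- fix_flux(m, m$roles$glucose_exchange, -1)
#' @export
fix_flux <- function(model, reaction_id, value) {
  set_bounds(model, reaction_id, value, value)
}

#' Set the bounds of a reaction
#'
#' @inheritParams fix_flux
#' @param lb,ub New lower and upper bounds (lb <= ub).
#' @return Edited copy of the model.
#' @export
set_bounds <- function(model, reaction_id, lb, ub) {
  i <- match(reaction_id, model$reactions$id)
  if (is.na(i)) abort(paste0("no such reaction: '", reaction_id, "'"))
  if (lb > ub) abort(paste0("lb > ub for '", reaction_id, "'"))
  model$reactions$lower_bound[i] <- as.numeric(lb)
  model$reactions$upper_bound[i] <- as.numeric(ub)
  model
}

# Fix the objective at its optimum (within rel_tol) and return the edited
# model together with the optimum value.
fix_at_optimum <- function(model, objective, sense = "max", rel_tol = 1e-9) {
  sol <- solve_fba(model, objective, sense)
  if (sol$status != "optimal") return(list(model = NULL, solution = sol))
  opt <- sol$objective_value
  slack <- rel_tol * max(1, abs(opt))
  m2 <- if (sense == "max") {
    set_bounds(model, objective, opt - slack,
               model$reactions$upper_bound[match(objective, model$reactions$id)])
  } else {
    set_bounds(model, objective,
               model$reactions$lower_bound[match(objective, model$reactions$id)],
               opt + slack)
  }
  list(model = m2, solution = sol)
}

#' Flux range of one reaction at the optimum of another (FVA)
#'
#' Fixes the primary objective at its optimum (to within `rel_tol`
#' relative), then minimises and maximises the target flux. This resolves
#' the alternate-optima ambiguity when a single flux at an optimum is to be
#' reported.
#'
#' @param model A `metabolic_model`.
#' @param objective Primary objective reaction id.
#' @param target Reaction whose flux range is wanted.
#' @param sense Sense of the primary objective.
#' @param rel_tol Relative slack allowed on the primary optimum.
#' @return Tibble with columns `target`, `min`, `max`; zero rows with a
#'   status attribute if the primary problem is not optimal.
#' @export
flux_range_at_optimum <- function(model, objective, target,
                                  sense = "max", rel_tol = 1e-9) {
  fx <- fix_at_optimum(model, objective, sense, rel_tol)
  if (is.null(fx$model)) {
    out <- tibble(target = character(), min = numeric(), max = numeric())
    attr(out, "status") <- fx$solution$status
    return(out)
  }
  lo <- solve_fba(fx$model, target, "min")
  hi <- solve_fba(fx$model, target, "max")
  tibble(target = target, min = lo$objective_value, max = hi$objective_value)
}

#' Parsimonious representative optimum (pFBA)
#'
#' Solves the primary objective, fixes it at the optimum, then minimises the
#' total absolute flux sum |v|. The result is a canonical, deterministic
#' optimum free of futile cycles, suitable for reporting single flux values.
#' Absolute values are handled by the standard split into non-negative
#' forward and reverse parts.
#'
#' @inheritParams solve_fba
#' @return A `flux_solution`; `objective_value` is the primary optimum, and
#'   the fluxes are the parsimonious vector.
#' @export
parsimonious_refine <- function(model, objective = NULL,
                                sense = c("max", "min")) {
  sense <- match.arg(sense)
  objective <- objective %||% model$roles$biomass
  fx <- fix_at_optimum(model, objective, sense)
  if (is.null(fx$model)) return(fx$solution)
  m2 <- fx$model
  S <- as.matrix(stoichiometric_matrix(m2))
  b <- model_bounds(m2)
  lb <- pmax(b$lb, -.FLUX_BIG); ub <- pmin(b$ub, .FLUX_BIG)
  n <- ncol(S)
  # split into irreversible forward/reverse parts: v = f - r, f, r >= 0;
  # min sum(f + r) recovers the minimal total |v| among the fixed optima
  A <- cbind(S, -S)
  lb_f <- pmax(lb, 0); ub_f <- pmax(ub, 0)
  lb_r <- pmax(-ub, 0); ub_r <- pmax(-lb, 0)
  res <- simplex_box(A, rep(0, nrow(S)), rep(1, 2L * n),
                     c(lb_f, lb_r), c(ub_f, ub_r), "min")
  if (res$status != "optimal") {
    # fall back to the unrefined solution rather than failing the caller
    return(fx$solution)
  }
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  names(v) <- m2$reactions$id
  residual <- max(abs(as.numeric(S %*% v)))
  new_flux_solution("optimal", objective, sense, unname(v[objective]), v,
                    residual)
}
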