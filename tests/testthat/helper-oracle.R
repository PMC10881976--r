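# Independent brute-force LP oracle: enumerates every basic solution of
# {A v = 0, lb <= v <= ub} (choose n - m variables pinned at a bound, solve
# for the rest) and returns the best feasible objective. Exponential, so only
# for small fixtures; deliberately shares no code with the simplex engine.
brute_lp <- function(A, cost, lb, ub, sense = "max") {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  best <- NA_real_
  consider <- function(v) {
    if (all(v >= lb - 1e-8) && all(v <= ub + 1e-8)) {
      val <- sum(cost * v)
      if (is.na(best) ||
          (sense == "max" && val > best) ||
          (sense == "min" && val < best)) best <<- val
    }
  }
  if (m == 0L) {
    consider(ifelse(sense == "max", ifelse(cost > 0, ub, lb),
                    ifelse(cost > 0, lb, ub)))
    return(best)
  }
  for (free in utils::combn(n, n - m, simplify = FALSE)) {
    basic <- setdiff(seq_len(n), free)
    B <- A[, basic, drop = FALSE]
    if (nrow(B) != ncol(B) || abs(det(B)) < 1e-10) next
    grid <- expand.grid(rep(list(1:2), length(free)))
    for (g in seq_len(nrow(grid))) {
      vF <- ifelse(unlist(grid[g, ]) == 1, lb[free], ub[free])
      vB <- solve(B, -A[, free, drop = FALSE] %*% vF)
      v <- numeric(n); v[free] <- vF; v[basic] <- vB
      consider(v)
    }
  }
  best
}

# brute-force FBA on a small model, via the oracle above
brute_fba <- function(model, objective, sense = "max", fixes = list()) {
  for (nm in names(fixes)) model <- fix_flux(model, nm, fixes[[nm]])
  S <- as.matrix(stoichiometric_matrix(model))
  lb <- pmax(model$reactions$lower_bound, -1000)
  ub <- pmin(model$reactions$upper_bound, 1000)
  cost <- as.numeric(model$reactions$id == objective)
  brute_lp(S, cost, lb, ub, sense)
}

# 4-reaction fixture with a futile cycle through the target reaction:
# uptake -> A, A -> B (R1), B -> A (R2, reversible loop), B -> out.
futile_cycle_model <- function(cycle_cap = 5) {
  mets <- dplyr::bind_rows(
    metabolite("A", formula = "CH2O"),
    metabolite("B", formula = "CH2O")
  )
  rxns <- dplyr::bind_rows(
    reaction("EX_A", c(A = -1), lower_bound = -1, upper_bound = 0,
             is_exchange = TRUE),
    reaction("R1", c(A = -1, B = 1), lower_bound = 0, upper_bound = cycle_cap),
    reaction("R2", c(B = -1, A = 1), lower_bound = 0, upper_bound = cycle_cap),
    reaction("EX_B", c(B = -1), lower_bound = 0, upper_bound = 1000,
             is_exchange = TRUE)
  )
  metabolic_model(mets, rxns, provenance = "futile cycle fixture")
}

# parallel-path fixture: direct A -> B, or the longer A -> C -> B detour
parallel_path_model <- function() {
  mets <- dplyr::bind_rows(
    metabolite("A", formula = "CH2O"),
    metabolite("B", formula = "CH2O"),
    metabolite("C", formula = "CH2O")
  )
  rxns <- dplyr::bind_rows(
    reaction("EX_A", c(A = -1), lower_bound = -1, upper_bound = 0,
             is_exchange = TRUE),
    reaction("DIRECT", c(A = -1, B = 1), lower_bound = 0),
    reaction("DETOUR1", c(A = -1, C = 1), lower_bound = 0),
    reaction("DETOUR2", c(C = -1, B = 1), lower_bound = 0),
    reaction("EX_B", c(B = -1), lower_bound = 0, is_exchange = TRUE)
  )
  metabolic_model(mets, rxns, provenance = "parallel path fixture")
}
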