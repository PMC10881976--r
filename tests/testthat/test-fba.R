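test_that("FBA solves the toy chain to its closed-form optimum", {
  m <- build_toy_linear_model()
  sol <- solve_fba(m, "EX_P", "max")
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 1, tolerance = 1e-9)
  expect_lte(sol$steady_state_residual, 1e-6)
  # fluxes respect bounds
  expect_true(all(sol$fluxes >= m$reactions$lower_bound - 1e-9))
  expect_true(all(sol$fluxes <= m$reactions$upper_bound + 1e-9))
  td <- tidy(sol)
  expect_equal(td$flux[td$reaction == "EX_P"], 1, tolerance = 1e-9)
  expect_equal(glance(sol)$status, "optimal")
})

test_that("infeasible and missing-objective cases are reported, not thrown", {
  m <- build_toy_linear_model()
  m2 <- fix_flux(m, "EX_S", -1) |> set_bounds("CONV", 0, 0)
  sol <- solve_fba(m2, "EX_P", "max")
  expect_equal(sol$status, "infeasible")
  expect_error(solve_fba(m, "NOPE"), "not in model")
  expect_error(solve_fba(metabolic_model(m$metabolites, m$reactions)),
               "no objective")
})

test_that("fixing fluxes pins bounds and edits are pure", {
  m <- build_core_model()
  m2 <- fix_flux(m, "EX_glc", -1)
  i <- match("EX_glc", m2$reactions$id)
  expect_equal(m2$reactions$lower_bound[i], -1)
  expect_equal(m2$reactions$upper_bound[i], -1)
  # original untouched
  expect_equal(m$reactions$lower_bound[match("EX_glc", m$reactions$id)], -10)
  # fixed flux is honoured exactly in the solution
  sol <- solve_fba(m2, "BIOMASS", "max")
  expect_equal(sol$fluxes[["EX_glc"]], -1, tolerance = 1e-12)
  # knockout
  m3 <- set_bounds(m, "PYC", 0, 0)
  solk <- solve_fba(fix_flux(m3, "EX_glc", -1), "BIOMASS", "max")
  expect_equal(solk$fluxes[["PYC"]], 0)
  expect_error(set_bounds(m, "PYC", 1, -1), "lb > ub")
})

test_that("core-model ATP audit matches the respiratory stoichiometry", {
  audit <- function(po) {
    m <- build_core_model(core_model_config(po_ratio = po))
    m <- fix_flux(m, "EX_glc", -1) |> fix_flux("BIOMASS", 0)
    solve_fba(m, "ATPM", "max")$objective_value
  }
  # 4 substrate-level + 12 respiratory ATP at P/O = 1
  expect_equal(audit(1), 16, tolerance = 1e-6)
  # 4 + 12 x 1.5 at P/O = 1.5 (hand stoichiometric audit)
  expect_equal(audit(1.5), 22, tolerance = 1e-6)
})

test_that("3-HP production requires a bicarbonate source", {
  m <- add_3hp_pathway(build_core_model())
  closed <- cap_bicarbonate_formation(m, 0) |>
    set_bounds("EX_hco3", 0, 1000) |>
    fix_flux("EX_glc", -1) |> fix_flux("BIOMASS", 0)
  sol <- solve_fba(closed, "EX_3hp", "max")
  expect_equal(sol$objective_value, 0, tolerance = 1e-9)
})

test_that("flux ranges at the optimum expose alternate optima", {
  # unique optimum: range collapses
  m <- build_toy_linear_model()
  r <- flux_range_at_optimum(m, "EX_P", "CONV")
  expect_equal(r$min, r$max, tolerance = 1e-9)
  expect_equal(r$min, 1, tolerance = 1e-9)
  # futile cycle through the target leaves a strictly positive range
  fc <- futile_cycle_model(cycle_cap = 5)
  r2 <- flux_range_at_optimum(fc, "EX_B", "R1")
  expect_gt(r2$max - r2$min, 1)
  # brute-force confirmation of both ends
  fx <- fluxenv:::fix_at_optimum(fc, "EX_B", "max")
  expect_equal(r2$min, brute_fba(fx$model, "R1", "min"), tolerance = 1e-9)
  expect_equal(r2$max, brute_fba(fx$model, "R1", "max"), tolerance = 1e-9)
  # infeasible primary propagates status
  bad <- fix_flux(fc, "EX_A", -1) |> set_bounds("R1", 0, 0) |>
    set_bounds("R2", 0, 0)
  rr <- flux_range_at_optimum(bad, "EX_B", "R1")
  expect_equal(nrow(rr), 0L)
  expect_equal(attr(rr, "status"), "infeasible")
})

test_that("parsimonious refinement picks the shortest route", {
  pp <- parallel_path_model()
  sol <- parsimonious_refine(pp, "EX_B", "max")
  expect_equal(sol$objective_value, 1, tolerance = 1e-9)
  # brute force over the two alternatives: direct (total |v| = 3) beats the
  # detour (total |v| = 4)
  expect_equal(sol$fluxes[["DIRECT"]], 1, tolerance = 1e-9)
  expect_equal(sol$fluxes[["DETOUR1"]], 0, tolerance = 1e-9)
  # futile cycle is suppressed in the parsimonious optimum
  fc <- futile_cycle_model()
  solfc <- parsimonious_refine(fc, "EX_B", "max")
  expect_equal(solfc$fluxes[["R2"]], 0, tolerance = 1e-9)
  # unique-optimum model: identical to the plain solution
  tm <- build_toy_linear_model()
  expect_equal(parsimonious_refine(tm, "EX_P")$fluxes,
               solve_fba(tm, "EX_P")$fluxes, tolerance = 1e-8)
  # refined objective equals the unrefined optimum
  expect_equal(parsimonious_refine(fc, "EX_B")$objective_value,
               solve_fba(fc, "EX_B")$objective_value, tolerance = 1e-7)
})

test_that("simplex agrees with the brute-force oracle on all small models", {
  models <- list(build_toy_linear_model(), build_toy_branch_model(),
                 futile_cycle_model(), parallel_path_model())
  for (m in models) {
    for (obj in m$reactions$id) {
      for (sense in c("max", "min")) {
        bf <- brute_fba(m, obj, sense)
        sol <- solve_fba(m, obj, sense)
        expect_equal(sol$objective_value, bf, tolerance = 1e-9,
                     label = paste(m$provenance, obj, sense))
      }
    }
  }
})

test_that("simplex agrees with brute force on random bounded LPs", {
  set.seed(7)
  for (trial in 1:40) {
    n <- sample(3:6, 1); m <- sample(1:(n - 1), 1)
    A <- matrix(sample(-2:2, m * n, TRUE), m, n)
    lb <- round(runif(n, -4, 0), 1); ub <- round(runif(n, 0, 4), 1)
    cost <- round(runif(n, -2, 2), 1)
    sense <- sample(c("max", "min"), 1)
    bf <- brute_lp(A, cost, lb, ub, sense)
    sx <- fluxenv:::simplex_box(A, rep(0, m), cost, lb, ub, sense)
    if (is.na(bf)) {
      expect_true(sx$status != "optimal")
    } else {
      expect_equal(sx$value, bf, tolerance = 1e-9)
    }
  }
})

test_that("the LP optimum is concave in a single bound (max sense)", {
  m <- build_toy_branch_model()
  caps <- seq(0, 1, length.out = 9)
  vals <- vapply(caps, function(u) {
    solve_fba(set_bounds(m, "GROWTH", 0, u) |> fix_flux("EX_S", -1),
              "EX_P", "max")$objective_value
  }, 1)
  d2 <- diff(diff(vals))
  expect_true(all(d2 <= 1e-9))
})

test_that("every FBA solution on the core model conserves exchanged carbon", {
  m <- add_3hp_pathway(build_core_model())
  set.seed(11)
  for (trial in 1:8) {
    ratio <- sample(c(0, 0.3, 1, Inf), 1)
    obj <- sample(c("EX_3hp", "BIOMASS", "ATPM", "EX_etoh"), 1)
    m2 <- cap_bicarbonate_formation(m, ratio) |> fix_flux("EX_glc", -1)
    sol <- solve_fba(m2, obj, "max")
    expect_equal(sol$status, "optimal")
    expect_lte(abs(carbon_exchange_balance(m2, sol)), 1e-6)
    expect_lte(sol$steady_state_residual, 1e-6)
  }
})
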