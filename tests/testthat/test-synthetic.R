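test_that("the core model is balanced and grows aerobically", {
  m <- build_core_model()
  expect_true(validate_elemental_balance(m)$pass)
  sol <- solve_fba(fix_flux(m, "EX_glc", -1), "BIOMASS", "max")
  expect_equal(sol$status, "optimal")
  expect_gt(sol$objective_value, 0)
})

test_that("the ethanol branch sustains anaerobic growth (Crabtree regime)", {
  m <- build_core_model()
  anaerobic <- fix_flux(m, "EX_o2", 0) |> fix_flux("EX_glc", -1)
  sol <- solve_fba(anaerobic, "BIOMASS", "max")
  expect_equal(sol$status, "optimal")
  expect_gt(sol$objective_value, 0)
  # fermentation is strictly worse than respiration
  aerobic <- solve_fba(fix_flux(m, "EX_glc", -1), "BIOMASS", "max")
  expect_lt(sol$objective_value, aerobic$objective_value)
})

test_that("the phosphoketolase bypass strictly raises the 3-HP ceiling", {
  with_pk <- add_3hp_pathway(build_core_model())
  no_pk <- add_3hp_pathway(build_core_model(
    core_model_config(include_pk = FALSE)))
  expect_gt(max_theoretical_yield(with_pk)$mol_per_mol,
            max_theoretical_yield(no_pk)$mol_per_mol)
})

test_that("config invariants are enforced", {
  expect_error(core_model_config(po_ratio = 0), "po_ratio")
  expect_error(core_model_config(gam = -1), "gam")
  # NGAM imposes a floor on the dissipation flux
  m <- build_core_model(core_model_config(ngam = 0.5))
  sol <- solve_fba(fix_flux(m, "EX_glc", -1), "BIOMASS", "max")
  expect_gte(sol$fluxes[["ATPM"]], 0.5 - 1e-9)
})

test_that("toy fixtures are small, balanced and analytically solvable", {
  lin <- build_toy_linear_model()
  br <- build_toy_branch_model()
  expect_lte(nrow(lin$reactions), 8L)
  expect_lte(nrow(br$reactions), 8L)
  expect_true(validate_elemental_balance(lin)$pass)
  expect_true(validate_elemental_balance(br)$pass)
  expect_equal(solve_fba(lin, "EX_P", "max")$objective_value, 1,
               tolerance = 1e-9)
  an <- analytic_envelope_toy()
  expect_equal(an$yield_product(0), an$yp_max)
  expect_equal(an$yield_product(an$mu_max), 0)
  # midpoint agrees with the LP envelope to 1e-9
  env <- compute_envelope(br, envelope_spec(bicarbonate_ratios = Inf,
                                            n_growth_points = 3))
  mid <- env[env$growth_fraction == 0.5, ]
  expect_equal(mid$yield_product, an$yield_product(mid$mu), tolerance = 1e-9)
})

test_that("synthetic strain tables are reproducible and recover the truth", {
  truth <- tibble::tibble(yield_product = c(0.1, 0.3, 0.5),
                          yield_biomass = c(0.05, 0.1, 0.2))
  # noiseless: titres are exactly truth x glucose
  t0 <- generate_strain_table(truth, glucose = 20, noise_cv = 0)
  expect_equal(t0$titre, truth$yield_product * 20)
  expect_equal(t0$dcw, truth$yield_biomass * 20)
  # fixed seed: identical output (and identical CSV bytes)
  t1 <- generate_strain_table(truth, noise_cv = 0.05, seed = 99)
  t2 <- generate_strain_table(truth, noise_cv = 0.05, seed = 99)
  expect_identical(t1, t2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(t1, f1, row.names = FALSE)
  utils::write.csv(t2, f2, row.names = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # heavy noise on tiny yields clips at zero with a warning
  tiny <- tibble::tibble(yield_product = 0.001, yield_biomass = 0.001)
  expect_warning(generate_strain_table(tiny[rep(1, 50), ], noise_cv = 1,
                                       seed = 3), "clipped")
  expect_error(generate_strain_table(
    tibble::tibble(yield_product = -1, yield_biomass = 0)), ">= 0")
})

test_that("noiseless overlays reproduce the generating yields exactly", {
  m <- add_3hp_pathway(build_core_model())
  env <- compute_envelope(m, envelope_spec(bicarbonate_ratios = Inf,
                                           n_growth_points = 11))
  truth <- tibble::tibble(yield_product = c(0.2, 0.4),
                          yield_biomass = c(0.1, 0.05))
  tab <- generate_strain_table(truth, glucose = 20, noise_cv = 0)
  ov <- overlay_strains(tab, env)
  expect_equal(ov$yield_product, truth$yield_product, tolerance = 1e-12)
  expect_equal(ov$yield_biomass, truth$yield_biomass, tolerance = 1e-12)
})

test_that("mean yields from noisy tables converge to the truth", {
  truth <- tibble::tibble(yield_product = rep(0.4, 200),
                          yield_biomass = rep(0.15, 200))
  tab <- generate_strain_table(truth, glucose = 20, noise_cv = 0.05,
                               seed = 123)
  expect_lt(abs(mean(tab$titre / tab$glucose) - 0.4) / 0.4, 0.01)
  expect_lt(abs(mean(tab$dcw / tab$glucose) - 0.15) / 0.15, 0.01)
})

test_that("the packaged endpoint table loads with the expected shape", {
  se <- strain_endpoints()
  expect_true(all(c("strain", "titre", "glucose", "od600") %in% names(se)))
  expect_true(all(se$glucose == 20))
  expect_equal(se$titre[se$strain == "QLW71"], 11.25)
})
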