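test_that("the toy branch envelope matches its closed form to 1e-9", {
  m <- build_toy_branch_model()
  an <- analytic_envelope_toy()
  env <- compute_envelope(m, envelope_spec(bicarbonate_ratios = Inf,
                                           n_growth_points = 9))
  expect_true(all(env$feasible))
  # mu grid spans [0, mu_max]
  expect_equal(max(env$mu), an$mu_max, tolerance = 1e-9)
  # upper envelope is the analytic line, in flux and in yield coordinates
  expect_equal(env$product_max, an$product_flux(env$mu), tolerance = 1e-9)
  expect_equal(env$yield_product, an$yield_product(env$mu), tolerance = 1e-9)
  # endpoints: full yield at zero growth, zero at mu_max
  expect_equal(env$yield_product[env$growth_fraction == 0], an$yp_max,
               tolerance = 1e-9)
  expect_equal(env$yield_product[env$growth_fraction == 1], 0,
               tolerance = 1e-9)
  # biomass yield reaches the 1:1 Cmol limit at mu_max
  expect_equal(max(env$yield_biomass), an$yb_max, tolerance = 1e-9)
})

test_that("closing all bicarbonate flattens the 3-HP envelope to zero", {
  m <- add_3hp_pathway(build_core_model())
  env <- compute_envelope(m, envelope_spec(bicarbonate_ratios = 0,
                                           n_growth_points = 7))
  expect_true(all(abs(env$product_max) <= 1e-8))
})

test_that("the upper envelope is concave and monotone in the ratio", {
  m <- add_3hp_pathway(build_core_model())
  env <- compute_envelope(m, envelope_spec(
    bicarbonate_ratios = c(0.25, 0.5, 1, Inf), n_growth_points = 11))
  expect_true(all(env$feasible))
  for (rt in unique(env$ratio)) {
    g <- env[env$ratio == rt, ]
    g <- g[order(g$mu), ]
    d2 <- diff(diff(g$product_max)) / diff(g$mu)[1]^2
    expect_true(all(d2 <= 1e-6), label = paste("concavity at ratio", rt))
  }
  # product_max at fixed growth fraction is non-decreasing in the ratio
  wide <- tidyr::pivot_wider(
    dplyr::select(as_tibble(env), "ratio", "growth_fraction", "product_max"),
    names_from = "ratio", values_from = "product_max")
  mats <- as.matrix(wide[, -1])
  expect_true(all(apply(mats, 1, function(x) all(diff(x) >= -1e-8))))
})

test_that("refining the growth grid keeps shared points identical", {
  m <- add_3hp_pathway(build_core_model())
  coarse <- compute_envelope(m, envelope_spec(bicarbonate_ratios = Inf,
                                              n_growth_points = 5))
  fine <- compute_envelope(m, envelope_spec(bicarbonate_ratios = Inf,
                                            n_growth_points = 21))
  shared <- intersect(coarse$growth_fraction, fine$growth_fraction)
  expect_equal(sort(shared), c(0, 0.25, 0.5, 0.75, 1))
  for (f in shared) {
    expect_equal(coarse$product_max[coarse$growth_fraction == f],
                 fine$product_max[fine$growth_fraction == f],
                 tolerance = 1e-9)
  }
})

test_that("maximum theoretical yield reports consistent molar/mass units", {
  m <- add_3hp_pathway(build_core_model())
  y <- max_theoretical_yield(m)
  expect_equal(y$g_per_g, y$mol_per_mol * formula_weight("C3H6O3") /
                 formula_weight("C6H12O6"), tolerance = 1e-12)
  # matches the zero-growth envelope point
  env <- compute_envelope(m, envelope_spec(bicarbonate_ratios = Inf,
                                           n_growth_points = 5))
  expect_equal(y$product_flux, env$product_max[env$growth_fraction == 0],
               tolerance = 1e-8)
  # fully closed bicarbonate: yield 0
  y0 <- max_theoretical_yield(cap_bicarbonate_formation(m, 0) |>
                                set_bounds("EX_hco3", 0, 1000))
  expect_equal(y0$mol_per_mol, 0, tolerance = 1e-9)
})

test_that("the bicarbonate:glucose ratio at the optimum equals the molar yield", {
  m <- add_3hp_pathway(build_core_model())
  y <- max_theoretical_yield(m)
  r <- bicarbonate_ratio_at_optimum(m)
  # 1:1 carboxylation makes supply ratio = molar product yield
  expect_equal(r$ratio, y$mol_per_mol, tolerance = 1e-6)
  # alternate optima do not move the required supply here
  expect_equal(r$ratio_min, r$ratio_max, tolerance = 1e-6)
  # when the cap binds below the unconstrained demand, the ratio equals it
  capped <- cap_bicarbonate_formation(m, 0.5)
  r5 <- bicarbonate_ratio_at_optimum(capped)
  expect_equal(r5$ratio, 0.5, tolerance = 1e-6)
})

test_that("strain overlays map endpoints to yields and classify them", {
  m <- add_3hp_pathway(build_core_model())
  env <- compute_envelope(m, envelope_spec(bicarbonate_ratios = c(0.5, Inf),
                                           n_growth_points = 11))
  # a strain generated inside the envelope is classified inside
  inside <- generate_strain_table(
    tibble::tibble(yield_product = 0.1, yield_biomass = 0.1), noise_cv = 0)
  ov <- overlay_strains(inside, env)
  expect_true(all(ov$status[ov$ratio == Inf] == "inside"))
  # a flask endpoint: 11.25 g/L on 20 g/L glucose -> 0.5625 g/g
  flask <- tibble::tibble(strain = "S71", titre = 11.25, glucose = 20,
                          od600 = 10)
  # at that biomass yield the flask endpoint beats the core-model envelope
  expect_warning(ov2 <- overlay_strains(flask, env), "outside")
  expect_equal(unique(ov2$yield_product), 0.5625)
  # DCW imputed as 0.7 x OD600
  expect_equal(unique(ov2$yield_biomass), 0.7 * 10 / 20)
  # a yield above every envelope is outside, with a warning
  high <- tibble::tibble(strain = "X", titre = 19, glucose = 20, dcw = 2)
  expect_warning(ov3 <- overlay_strains(high, env), "outside")
  expect_true(all(ov3$status == "outside"))
  # non-positive glucose is an error naming the row
  expect_error(overlay_strains(
    tibble::tibble(strain = "Z", titre = 1, glucose = 0, dcw = 1), env),
    "glucose")
})
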