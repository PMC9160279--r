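test_that("carbohydrates split 50/50 into CH4 and CO2", {
  glu <- boyle_coefficients(elemental_formula(6, 12, 6))
  expect_equal(glu$water_coeff, 0)
  expect_equal(glu$ch4_coeff, 3)
  expect_equal(glu$co2_coeff, 3)
  expect_identical(unname(gas_composition(glu)[["CH4"]]), 0.5)
  expect_identical(unname(gas_composition(glu, FALSE)[["CH4"]]), 0.5)

  cel <- boyle_coefficients(elemental_formula(6, 10, 5))
  expect_equal(cel$water_coeff, 1)
  expect_equal(cel$ch4_coeff, 3)
  expect_equal(cel$co2_coeff, 3)
})

test_that("sludge formula reproduces the element-balance solution", {
  f <- sludge_formula()
  s <- boyle_coefficients(f)
  oracle <- balance_oracle(f)
  expect_equal(s$water_coeff, oracle[["water"]], tolerance = 1e-12)
  expect_equal(s$ch4_coeff, oracle[["ch4"]], tolerance = 1e-12)
  expect_equal(s$co2_coeff, oracle[["co2"]], tolerance = 1e-12)
  expect_equal(s$ch4_coeff, 2.011, tolerance = 1e-3)
  expect_equal(s$co2_coeff, 1.751, tolerance = 1e-3)
  # composition with and without the trace gases
  expect_equal(unname(gas_composition(s)[["CH4"]]), 0.497, tolerance = 1e-3)
  expect_equal(unname(gas_composition(s, FALSE)[["CH4"]]), 0.535,
               tolerance = 1e-3)
})

test_that("closed forms agree with the linear-system oracle on random formulas", {
  set.seed(42)
  for (i in 1:200) {
    f <- random_formula()
    s <- boyle_coefficients(f)
    oracle <- balance_oracle(f)
    expect_equal(
      c(s$water_coeff, s$ch4_coeff, s$co2_coeff, s$nh3_coeff, s$h2s_coeff),
      unname(oracle), tolerance = 1e-10
    )
    expect_equal(unname(sum(s$gas_fractions)), 1, tolerance = 1e-12)
    expect_equal(s$ch4_coeff + s$co2_coeff, f$a, tolerance = 1e-9)
  }
})

test_that("nitrogen- and sulfur-free formulas reduce to the Buswell case", {
  f <- elemental_formula(5, 9, 2.5)
  s <- boyle_coefficients(f)
  expect_identical(s$nh3_coeff, 0)
  expect_identical(s$h2s_coeff, 0)
  expect_equal(s$ch4_coeff, 5 / 2 + 9 / 8 - 2.5 / 4)
})

test_that("infeasibly oxidized or reduced feedstocks are rejected", {
  # oxalate-like carbon (CO3 stoichiometry): negative methane coefficient
  expect_error(boyle_coefficients(elemental_formula(1, 0, 3)),
               class = "biogasim_infeasible_feedstock")
  # more hydrogen than methane itself: negative CO2 coefficient
  expect_error(boyle_coefficients(elemental_formula(1, 6, 0)),
               class = "biogasim_infeasible_feedstock")
})

test_that("theoretical methane yield scales with molar volume and basis", {
  glu <- elemental_formula(6, 12, 6)
  y <- theoretical_methane_yield(glu)
  expect_equal(unname(y[["per_kg"]]), 3 * 22.414 / 0.18016, tolerance = 1e-3)
  y2 <- theoretical_methane_yield(glu, molar_volume = 2 * 22.414)
  expect_equal(unname(y2[["per_kg"]]), 2 * unname(y[["per_kg"]]))

  f <- sludge_formula()
  ys <- theoretical_methane_yield(f)
  expect_equal(unname(ys[["per_kg"]]), 450.8, tolerance = 1e-3)
  yvs <- theoretical_methane_yield(f, vs_frac = 0.5)
  expect_equal(unname(yvs[["per_kg_vs"]]), 2 * unname(yvs[["per_kg"]]))
})
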