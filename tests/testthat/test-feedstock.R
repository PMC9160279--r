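test_that("characterized sludge table loads with correct fractions", {
  ua <- sludge_ua()
  expect_s3_class(ua, "ultimate_analysis")
  expect_equal(ua$c_frac, 0.4519)
  expect_equal(ua$h_frac, 0.07299)
  expect_equal(ua$n_frac, 0.03579)
  expect_equal(ua$s_frac, 0.0094)
  expect_equal(ua$o_frac, 0.42992)
  expect_equal(ua$c_frac + ua$h_frac + ua$n_frac + ua$s_frac + ua$o_frac, 1)
})

test_that("single-element and missing-element records behave as documented", {
  one <- load_ultimate_analysis(data.frame(element = "C", percent = 100))
  expect_equal(one$c_frac, 1)
  expect_equal(one$h_frac + one$n_frac + one$s_frac + one$o_frac, 0)
  expect_error(
    load_ultimate_analysis(data.frame(element = "C", percent = 100),
                           strict = TRUE),
    "missing element row: H"
  )
  expect_error(
    load_ultimate_analysis(data.frame(element = c("C", "X"),
                                      percent = c(50, 50))),
    "unknown element"
  )
})

test_that("closure violations are rejected", {
  expect_error(
    load_ultimate_analysis(data.frame(element = c("C", "O"),
                                      percent = c(40, 40))),
    "closure"
  )
  expect_error(ultimate_analysis(0.4, 0.05, 0.02, 0.01, 0.3), "closure")
  expect_error(ultimate_analysis(0, 0.1, 0.05, 0.01, 0.84), "carbon")
})

test_that("empirical formula matches per-element hand division", {
  f <- sludge_formula(100)
  # mass / atomic weight, computed by hand with 4-decimal IUPAC weights
  expect_equal(f$a, 45.19 / 12.011, tolerance = 1e-12)
  expect_equal(f$b, 7.299 / 1.008, tolerance = 1e-12)
  expect_equal(f$c, 42.992 / 15.999, tolerance = 1e-12)
  expect_equal(f$d, 3.579 / 14.007, tolerance = 1e-12)
  expect_equal(f$e, 0.94 / 32.06, tolerance = 1e-12)
  expect_equal(f$a, 3.762, tolerance = 1e-3)
  expect_equal(f$b, 7.241, tolerance = 1e-3)
})

test_that("a pure-methane composition gives a 4:1 H:C mole ratio", {
  ua <- load_ultimate_analysis(data.frame(element = c("C", "H"),
                                          percent = c(74.87, 25.13)))
  f <- to_empirical_formula(ua, 100)
  expect_equal(f$b / f$a, 4, tolerance = 0.01 / 4)
})

test_that("formula is exactly linear in basis mass and round-trips", {
  ua <- sludge_ua()
  f1 <- to_empirical_formula(ua, 1)
  f100 <- to_empirical_formula(ua, 100)
  for (fld in c("a", "b", "c", "d", "e")) {
    expect_identical(f100[[fld]], 100 * f1[[fld]])
  }
  # round trip: formula -> mass fractions -> formula
  fr <- formula_mass_fractions(f100)
  ua2 <- ultimate_analysis(fr[["C"]], fr[["H"]], fr[["N"]], fr[["S"]],
                           fr[["O"]])
  f2 <- to_empirical_formula(ua2, 100)
  for (fld in c("a", "b", "c", "d", "e")) {
    expect_equal(f2[[fld]], f100[[fld]], tolerance = 1e-9)
  }
})

test_that("proximate table loads and VS fractions are consistent", {
  pa <- load_proximate_analysis(sludge_proximate_path())
  expect_equal(pa$moisture, 6.3)
  expect_equal(pa$volatile_solid, 60.1)
  expect_equal(pa$ash, 27.0)
  expect_equal(vs_fraction(pa, "wet"), 0.601)
  expect_equal(vs_fraction(pa, "dry"), 60.1 / 93.7)
  expect_error(proximate_analysis(5, 40, 10, 5), "\\[95, 105\\]")
})
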