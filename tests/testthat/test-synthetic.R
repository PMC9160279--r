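test_that("feedstock generator reproduces the template at zero jitter", {
  tab <- generate_feedstock_table(seed = 1, n_samples = 1, jitter_frac = 0)
  expect_equal(tab$ultimate$percent, c(45.19, 3.579, 7.299, 0.94, 42.992))
  expect_equal(tab$proximate$percent, c(6.3, 60.1, 27.0, 6.7, 0.9))
})

test_that("jittered samples keep closure and are seed-reproducible", {
  a <- generate_feedstock_table(seed = 9, n_samples = 5, jitter_frac = 0.1)
  b <- generate_feedstock_table(seed = 9, n_samples = 5, jitter_frac = 0.1)
  expect_identical(a, b)
  sums <- tapply(a$ultimate$percent, a$ultimate$sample, sum)
  expect_true(all(abs(sums - 100) < 0.01))
  c_tab <- generate_feedstock_table(seed = 10, n_samples = 5,
                                    jitter_frac = 0.1)
  expect_false(identical(a$ultimate$percent, c_tab$ultimate$percent))
  expect_error(generate_feedstock_table(jitter_frac = 0.5), "0.2")
})

test_that("study generator is deterministic and cumulative-monotone", {
  d <- experiment_design(seed = 4)
  s1 <- generate_study(d)
  s2 <- generate_study(d)
  expect_identical(s1, s2)
  for (r in split(s1$cumulative_biogas, s1$reactor_id)) {
    expect_true(all(diff(r) >= 0))
  }
  expect_true(all(s1$methane_fraction >= 0 & s1$methane_fraction <= 1))
})

test_that("zero-noise observations equal the truth curve", {
  d <- experiment_design(noise_sd_frac = 0, replicates = 1, seed = 2)
  surf <- response_surface()
  s <- generate_study(d, surf)
  man <- truth_manifest(d, surf)
  opt <- s[s$ph == 8.5 & s$loading_ratio == "1:3" & s$temperature_c == 35, ]
  expect_equal(opt$cumulative_biogas,
               gompertz_cumulative(d$sampling_days, 100, 7.3, 5))
  # manifest at the optimum carries the unscaled base parameters
  row <- man[man$ph == 8.5 & man$loading_ratio == "1:3" &
               man$temperature_c == 35, ]
  expect_equal(row$multiplier, 1)
  expect_equal(row$b0, 100)
})

test_that("the response surface peaks at the designed optima", {
  d <- experiment_design(seed = 6)
  s <- generate_study(d)
  at35 <- s[s$temperature_c == 35 & s$day == 28, ]
  by_ph <- tapply(at35$cumulative_biogas[at35$loading_ratio == "1:3"],
                  at35$ph[at35$loading_ratio == "1:3"], mean)
  expect_equal(as.numeric(names(which.max(by_ph))), 8.5)
  by_load <- tapply(at35$cumulative_biogas[at35$ph == 8.5],
                    at35$loading_ratio[at35$ph == 8.5], mean)
  expect_equal(names(which.max(by_load)), "1:3")
  # thermophilic boundary: no production at 45 degC
  expect_true(all(s$cumulative_biogas[s$temperature_c == 45] == 0))
})

test_that("observation noise has roughly the nominal spread", {
  # monotonicity flooring takes the running maximum of near-asymptote
  # readings, which shrinks the terminal spread somewhat below the raw
  # noise sd; the estimate must still land within 30% of nominal
  day30 <- vapply(1:100, function(seed) {
    d <- experiment_design(seed = seed,
                           ph_levels = 8.5, loading_ratios = "1:3",
                           temperatures_c = 35)
    s <- generate_study(d)
    s$cumulative_biogas[s$day == 30]
  }, numeric(3))
  expect_equal(sd(day30), 2, tolerance = 0.3)
})

test_that("fitting a generated series recovers the manifest truth", {
  d <- experiment_design(seed = 12, sampling_days = 0:30)
  s <- generate_study(d)
  man <- truth_manifest(d)
  cond <- s[s$ph == 8.5 & s$loading_ratio == "1:3" & s$temperature_c == 35 &
              s$replicate == 1, ]
  fit <- fit_kinetics(cond)
  truth <- man[man$ph == 8.5 & man$loading_ratio == "1:3" &
                 man$temperature_c == 35, ]
  expect_lt(abs(fit$b0 - truth$b0) / truth$b0, 0.05)
})
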