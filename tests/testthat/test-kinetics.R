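test_that("Gompertz curve matches closed-form values and its asymptote", {
  expect_equal(gompertz_cumulative(5, b0 = 100, rmax = 10, lag = 5),
               100 * exp(-exp(1)))
  expect_equal(gompertz_cumulative(5, b0 = 100, rmax = 10, lag = 5), 6.60,
               tolerance = 1e-3)
  # far beyond lag + b0/rmax the curve is within 0.1% of b0
  expect_equal(gompertz_cumulative(5 + 100, b0 = 100, rmax = 10, lag = 5),
               100, tolerance = 1e-3)
  # monotone non-decreasing on a random grid
  set.seed(2)
  t <- sort(runif(50, 0, 60))
  b <- gompertz_cumulative(t, b0 = 80, rmax = 6, lag = 3)
  expect_true(all(diff(b) >= 0))
})

test_that("first-order curve obeys its identities", {
  expect_identical(first_order_cumulative(0, 100, 0.1), 0)
  expect_equal(first_order_cumulative(log(2) / 0.1, 100, 0.1), 50)
  expect_equal(first_order_cumulative(10, 100, 0.1), 100 * (1 - exp(-1)))
})

test_that("cumulative models stay in [0, b0] over random parameters", {
  set.seed(8)
  for (i in 1:50) {
    b0 <- runif(1, 10, 500)
    t <- sort(runif(40, 0, 100))
    g <- gompertz_cumulative(t, b0, runif(1, 0.5, 30), runif(1, 0, 10))
    f <- first_order_cumulative(t, b0, runif(1, 0.01, 1))
    expect_true(all(g >= 0 & g <= b0))
    expect_true(all(f >= 0 & f <= b0))
    expect_true(all(diff(g) >= 0) && all(diff(f) >= 0))
  }
})

test_that("CTMI temperature factor has the cardinal properties", {
  tr <- temperature_response()
  expect_identical(temperature_factor(35, tr), 1)
  expect_identical(temperature_factor(45, tr), 0)
  expect_identical(temperature_factor(10, tr), 0)
  expect_identical(temperature_factor(50, tr), 0)
  # direct formula evaluation at 25 degC with cardinal (10, 35, 45)
  num <- (25 - 45) * (25 - 10)^2
  den <- (35 - 10) * ((35 - 10) * (25 - 35) - (35 - 45) * (35 + 10 - 2 * 25))
  expect_equal(temperature_factor(25, tr), num / den)
  expect_gt(temperature_factor(25, tr), 0)
  expect_lt(temperature_factor(25, tr), 1)
  expect_error(temperature_response(35, 35, 45), "t_min < t_opt < t_max")
})

test_that("simulation scales the rate with temperature", {
  p <- batch_kinetics_params(100, rmax = 7.3, lag = 5)
  days <- 0:40
  at35 <- simulate_batch(p, days, 35)
  at25 <- simulate_batch(p, days, 25)
  at45 <- simulate_batch(p, days, 45)
  expect_equal(at35$cumulative_biogas, gompertz_cumulative(days, 100, 7.3, 5))
  # rmax-only scaling orders the curves pointwise from the lag onward;
  # before the lag both are a negligible sliver of b0
  post_lag <- days >= 5
  expect_true(all(at25$cumulative_biogas[post_lag] <=
                    at35$cumulative_biogas[post_lag]))
  expect_true(all(at25$cumulative_biogas[!post_lag] < 0.05 * 100))
  expect_true(all(at45$cumulative_biogas == 0))
  expect_false(attr(at45, "active"))
  # methane series is fraction x biogas
  expect_equal(at35$cumulative_methane, 0.41 * at35$cumulative_biogas)
  # slower kinetics: longer time to 95% of asymptote at 25 degC
  t95 <- function(s) s$day[which(s$cumulative_biogas >= 0.95 * 100)[1]]
  expect_gt(t95(at25), t95(at35))
})

test_that("fitting recovers exact parameters from noise-free data", {
  days <- 0:30
  obs <- data.frame(day = days,
                    cumulative_biogas = gompertz_cumulative(days, 100, 10, 5))
  fit <- fit_kinetics(obs)
  expect_true(attr(fit, "converged"))
  expect_equal(fit$b0, 100, tolerance = 1e-6)
  expect_equal(fit$rmax, 10, tolerance = 1e-6)
  expect_equal(fit$lag, 5, tolerance = 1e-6)

  obs1 <- data.frame(day = days,
                     cumulative_biogas = first_order_cumulative(days, 100, 0.1))
  fit1 <- fit_kinetics(obs1, model = "first_order")
  expect_equal(fit1$b0, 100, tolerance = 1e-6)
  expect_equal(fit1$k, 0.1, tolerance = 1e-6)
})

test_that("fitting rejects too-short series", {
  obs <- data.frame(day = 0:2, cumulative_biogas = c(0, 10, 20))
  expect_error(fit_kinetics(obs), "at least 4")
})

test_that("noisy triplicate fits recover b0 within 5%", {
  days <- 0:30
  truth <- gompertz_cumulative(days, 100, 10, 5)
  rel_err <- vapply(1:20, function(seed) {
    set.seed(seed)
    fits <- vapply(1:3, function(r) {
      y <- cummax(pmax(truth + rnorm(length(days), sd = 2), 0))
      fit_kinetics(data.frame(day = days, cumulative_biogas = y))$b0
    }, numeric(1))
    abs(mean(fits) - 100) / 100
  }, numeric(1))
  expect_lte(median(rel_err), 0.05)
})

test_that("optimal HRT matches closed forms under both criteria", {
  p1 <- batch_kinetics_params(100, k = 0.1, model = "first_order")
  expect_equal(optimal_hrt(p1, q = 0.95), log(20) / 0.1, tolerance = 0.01)
  expect_equal(optimal_hrt(p1, q = 0.99), log(100) / 0.1, tolerance = 0.01)
  # q -> 1 increases the HRT monotonically
  hrts <- vapply(c(0.5, 0.8, 0.95, 0.99), function(q) optimal_hrt(p1, q = q),
                 numeric(1))
  expect_true(all(diff(hrts) > 0))
  expect_error(optimal_hrt(p1, q = 1.2), "\\(0, 1\\)")

  # Gompertz peak daily rate at the inflection t = lag + b0/(rmax e)
  p2 <- batch_kinetics_params(100, rmax = 8, lag = 4)
  t_peak <- optimal_hrt(p2, criterion = "peak_daily_rate")
  expect_equal(t_peak, 4 + 100 / (8 * exp(1)), tolerance = 1e-4)
  # brute-force argmax of the finite-difference rate agrees
  grid <- seq(0, 40, 0.001)
  rate <- diff(gompertz_cumulative(grid, 100, 8, 4)) / diff(grid)
  expect_equal(t_peak, grid[which.max(rate)], tolerance = 0.01)
})

test_that("optimal HRT can be computed from a series and a temperature", {
  p <- batch_kinetics_params(100, rmax = 7.3, lag = 5)
  s <- simulate_batch(p, 0:40, temp = 35)
  expect_equal(optimal_hrt(s), optimal_hrt(p), tolerance = 0.02)
  expect_lt(optimal_hrt(p, temperature = 35), optimal_hrt(p, temperature = 25))
  expect_identical(optimal_hrt(p, temperature = 45), Inf)
})
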