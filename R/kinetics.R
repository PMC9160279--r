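# Batch digestion kinetics: cumulative-production models (modified
# Gompertz, first-order), a cardinal temperature response, simulation,
# nonlinear least-squares fitting, and optimal-HRT extraction.

#' Batch kinetic parameters
#'
#' Parameters of a saturating cumulative gas-production curve.
#'
#' @param b0 Ultimate cumulative yield (asymptote), in the volume units
#'   of the data.
#' @param rmax Maximum daily production rate (volume/day); required for
#'   the Gompertz model.
#' @param lag Lag time in days (>= 0).
#' @param k First-order rate constant (1/day); required for the
#'   first-order model.
#' @param model `"gompertz"` or `"first_order"`.
#' @return Object of class `batch_kinetics_params`.
#' @seealso [gompertz_cumulative()], [first_order_cumulative()],
#'   [fit_kinetics()]
#' @export
batch_kinetics_params <- function(b0, rmax = NULL, lag = 0, k = NULL,
                                  model = c("gompertz", "first_order")) {
  model <- match.arg(model)
  if (!is.finite(b0) || b0 <= 0) stop("b0 must be positive", call. = FALSE)
  if (!is.finite(lag) || lag < 0) stop("lag must be >= 0", call. = FALSE)
  if (model == "gompertz") {
    if (is.null(rmax) || !is.finite(rmax) || rmax <= 0) {
      stop("gompertz model needs rmax > 0", call. = FALSE)
    }
  } else {
    if (is.null(k) || !is.finite(k) || k <= 0) {
      stop("first-order model needs k > 0", call. = FALSE)
    }
  }
  structure(list(b0 = b0, rmax = rmax, lag = lag, k = k, model = model),
            class = "batch_kinetics_params")
}

#' @export
print.batch_kinetics_params <- function(x, ...) {
  if (x$model == "gompertz") {
    cat(sprintf("Modified Gompertz: b0 = %.4g, rmax = %.4g /day, lag = %.4g d\n",
                x$b0, x$rmax, x$lag))
  } else {
    cat(sprintf("First-order: b0 = %.4g, k = %.4g /day\n", x$b0, x$k))
  }
  invisible(x)
}

#' Modified Gompertz cumulative production
#'
#' \deqn{B(t) = B_0 \exp\{-\exp[\frac{R_{max} e}{B_0}(\lambda - t) + 1]\}}
#' A sigmoid rising from ~0 through an inflection to the asymptote
#' `b0`; `rmax` is the slope at the inflection and `lag` the intercept
#' of the steepest tangent with the time axis.
#'
#' @param t Time(s) in days, >= 0 (vectorized).
#' @param b0 Asymptotic cumulative yield.
#' @param rmax Maximum production rate (volume/day).
#' @param lag Lag time (days).
#' @return Cumulative production at `t`, same units as `b0`.
#' @export
#' @examples
#' gompertz_cumulative(0:30, b0 = 100, rmax = 10, lag = 5)
gompertz_cumulative <- function(t, b0, rmax, lag = 0) {
  if (any(t < 0)) stop("t must be >= 0 (days)", call. = FALSE)
  b0 * exp(-exp(rmax * exp(1) / b0 * (lag - t) + 1))
}

#' First-order cumulative production
#'
#' \deqn{B(t) = B_0 (1 - e^{-kt})}
#'
#' @param t Time(s) in days, >= 0.
#' @param b0 Asymptotic cumulative yield.
#' @param k Rate constant (1/day).
#' @return Cumulative production at `t`.
#' @export
first_order_cumulative <- function(t, b0, k) {
  if (any(t < 0)) stop("t must be >= 0 (days)", call. = FALSE)
  b0 * (1 - exp(-k * t))
}

#' Evaluate a cumulative model from a parameter object
#'
#' @param p A [batch_kinetics_params()].
#' @param t Times in days.
#' @return Cumulative production at `t`.
#' @export
cumulative_production <- function(p, t) {
  stopifnot(inherits(p, "batch_kinetics_params"))
  if (p$model == "gompertz") {
    gompertz_cumulative(t, p$b0, p$rmax, p$lag)
  } else {
    first_order_cumulative(t, p$b0, p$k)
  }
}

# analytic dB/dt, used by the peak-rate HRT criterion
.production_rate <- function(p, t) {
  if (p$model == "gompertz") {
    u <- p$rmax * exp(1) / p$b0 * (p$lag - t) + 1
    p$rmax * exp(1) * exp(u - exp(u))
  } else {
    p$b0 * p$k * exp(-p$k * t)
  }
}

#' Cardinal temperature response
#'
#' Describes the temperature range of the digesting community by its
#' cardinal temperatures: no activity at or below `t_min`, maximum at
#' `t_opt`, none at or above `t_max`.
#'
#' @param t_min,t_opt,t_max Temperatures in degC with
#'   `t_min < t_opt < t_max`. Defaults (10, 35, 45) place the optimum
#'   in the mesophilic range and make thermophilic 45 degC a dead
#'   boundary.
#' @return Object of class `temperature_response`.
#' @export
temperature_response <- function(t_min = 10, t_opt = 35, t_max = 45) {
  if (!(t_min < t_opt && t_opt < t_max)) {
    stop("cardinal temperatures must satisfy t_min < t_opt < t_max",
         call. = FALSE)
  }
  structure(list(t_min = t_min, t_opt = t_opt, t_max = t_max),
            class = "temperature_response")
}

#' Dimensionless temperature rate multiplier (CTMI)
#'
#' Cardinal temperature model with inflection:
#' \deqn{f(T) = \frac{(T - T_{max})(T - T_{min})^2}{(T_{opt} - T_{min})
#'   [(T_{opt} - T_{min})(T - T_{opt}) - (T_{opt} - T_{max})
#'   (T_{opt} + T_{min} - 2T)]}}
#' clipped to 0 outside `(t_min, t_max)`; `f(t_opt) = 1` by
#' construction.
#'
#' @param temp Temperature(s) in degC (vectorized).
#' @param tr A [temperature_response()].
#' @return Multiplier(s) in \[0, 1\].
#' @export
#' @examples
#' temperature_factor(c(25, 35, 45))
temperature_factor <- function(temp, tr = temperature_response()) {
  stopifnot(inherits(tr, "temperature_response"))
  tmin <- tr$t_min; topt <- tr$t_opt; tmax <- tr$t_max
  num <- (temp - tmax) * (temp - tmin)^2
  den <- (topt - tmin) *
    ((topt - tmin) * (temp - topt) - (topt - tmax) * (topt + tmin - 2 * temp))
  inside <- temp > tmin & temp < tmax
  if (any(inside & den == 0)) {
    stop("degenerate cardinal temperatures: CTMI denominator is zero",
         call. = FALSE)
  }
  f <- ifelse(inside, num / den, 0)
  pmin(pmax(f, 0), 1)
}

#' Simulate a deterministic batch digestion series
#'
#' Evaluates the cumulative model at the given sampling times with the
#' rate parameter (`rmax` or `k`) scaled by the CTMI temperature
#' multiplier, and derives the cumulative methane series as
#' `methane_fraction x biogas`. A temperature at or beyond the cardinal
#' limits produces the all-zero curve (the digester is inactive); this
#' is flagged, not an error.
#'
#' @param p A [batch_kinetics_params()].
#' @param times Sampling days, strictly increasing, >= 0.
#' @param temp Operating temperature, degC.
#' @param tr A [temperature_response()].
#' @param methane_fraction Methane mole fraction of the biogas, in
#'   \[0, 1\].
#' @param reactor_id,ph,loading_ratio Condition labels carried into the
#'   output.
#' @return A data frame (one row per sampling time) with columns
#'   `reactor_id`, `day`, `cumulative_biogas`, `cumulative_methane`,
#'   `methane_fraction`, `temperature_c`, `ph`, `loading_ratio`;
#'   attributes `temperature_factor` and `active`.
#' @export
#' @examples
#' p <- batch_kinetics_params(b0 = 100, rmax = 7.3, lag = 5)
#' simulate_batch(p, times = seq(0, 30, 5), temp = 25)
simulate_batch <- function(p, times, temp, tr = temperature_response(),
                           methane_fraction = 0.41, reactor_id = "sim",
                           ph = NA_real_, loading_ratio = NA_character_) {
  stopifnot(inherits(p, "batch_kinetics_params"))
  if (any(times < 0) || is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing and >= 0", call. = FALSE)
  }
  if (methane_fraction < 0 || methane_fraction > 1) {
    stop("methane_fraction must lie in [0, 1]", call. = FALSE)
  }
  f <- temperature_factor(temp, tr)
  if (f > 0) {
    ps <- p
    if (p$model == "gompertz") ps$rmax <- p$rmax * f else ps$k <- p$k * f
    biogas <- cumulative_production(ps, times)
  } else {
    biogas <- rep(0, length(times))
  }
  out <- data.frame(
    reactor_id = reactor_id,
    day = times,
    cumulative_biogas = biogas,
    cumulative_methane = methane_fraction * biogas,
    methane_fraction = methane_fraction,
    temperature_c = temp,
    ph = ph,
    loading_ratio = loading_ratio,
    stringsAsFactors = FALSE
  )
  attr(out, "temperature_factor") <- f
  attr(out, "active") <- f > 0
  out
}

#' Fit batch kinetic parameters to a cumulative time series
#'
#' Nonlinear least squares (Levenberg-Marquardt via
#' [minpack.lm::nlsLM()]) of the modified Gompertz or first-order model
#' to observed cumulative production. Starting values follow a fixed
#' strategy: `b0` at 1.2x the maximum observation, `rmax`/`k` from the
#' steepest finite difference, `lag` at the first time production
#' exceeds 5% of the maximum; the fit is therefore deterministic.
#'
#' @param series A data frame with columns `day` and
#'   `cumulative_biogas` (e.g. from [simulate_batch()] or
#'   [generate_study()]), at least 4 observations, volumes >= 0.
#' @param model `"gompertz"` or `"first_order"`.
#' @param init Optional named list overriding the automatic starting
#'   values (`b0`, `rmax`, `lag` or `b0`, `k`).
#' @return A [batch_kinetics_params()] with attributes `sse` (residual
#'   sum of squares), `std_errors` (per-parameter standard errors),
#'   `converged` (logical) and `fit` (the underlying `nls` object).
#' @export
#' @examples
#' obs <- simulate_batch(batch_kinetics_params(100, rmax = 10, lag = 5),
#'                       times = 0:30, temp = 35)
#' fit_kinetics(obs)
fit_kinetics <- function(series, model = c("gompertz", "first_order"),
                         init = NULL) {
  model <- match.arg(model)
  if (!is.data.frame(series) ||
      !all(c("day", "cumulative_biogas") %in% names(series))) {
    stop("series must be a data frame with columns day and cumulative_biogas",
         call. = FALSE)
  }
  t <- series$day
  y <- series$cumulative_biogas
  if (length(t) < 4) {
    stop("fitting needs at least 4 observations", call. = FALSE)
  }
  if (any(y < 0)) stop("cumulative volumes must be non-negative",
                       call. = FALSE)
  ymax <- max(y)
  if (ymax <= 0) stop("series is identically zero; nothing to fit",
                      call. = FALSE)
  rate0 <- max(diff(y) / diff(t))
  lag0 <- t[which(y > 0.05 * ymax)[1]]
  if (is.na(lag0)) lag0 <- 0
  dat <- data.frame(t = t, y = y)
  if (model == "gompertz") {
    start <- list(b0 = 1.2 * ymax, rmax = max(rate0, 1e-6), lag = lag0)
    if (!is.null(init)) start[names(init)] <- init
    fit <- try(minpack.lm::nlsLM(
      y ~ gompertz_cumulative(t, b0, rmax, lag), data = dat, start = start,
      lower = c(b0 = 1e-8, rmax = 1e-8, lag = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ), silent = TRUE)
  } else {
    start <- list(b0 = 1.2 * ymax, k = max(rate0 / ymax, 1e-6))
    if (!is.null(init)) start[names(init)] <- init
    fit <- try(minpack.lm::nlsLM(
      y ~ first_order_cumulative(t, b0, k), data = dat, start = start,
      lower = c(b0 = 1e-8, k = 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ), silent = TRUE)
  }
  if (inherits(fit, "try-error")) {
    stop(structure(
      class = c("biogasim_fit_error", "error", "condition"),
      list(message = paste0("kinetic fit did not converge from start values [",
                            paste(sprintf("%s=%.4g", names(start),
                                          unlist(start)), collapse = ", "),
                            "]: ", attr(fit, "condition")$message),
           call = NULL)
    ))
  }
  cf <- stats::coef(fit)
  p <- if (model == "gompertz") {
    batch_kinetics_params(cf[["b0"]], rmax = cf[["rmax"]], lag = cf[["lag"]])
  } else {
    batch_kinetics_params(cf[["b0"]], k = cf[["k"]], model = "first_order")
  }
  attr(p, "sse") <- sum(stats::resid(fit)^2)
  attr(p, "std_errors") <- tryCatch(
    summary(fit)$coefficients[, "Std. Error"],
    error = function(e) rep(NA_real_, length(cf))
  )
  attr(p, "converged") <- fit$convInfo$isConv
  attr(p, "fit") <- fit
  p
}

#' Optimal hydraulic retention time
#'
#' Extracts the retention time at which batch production is effectively
#' complete. Two criteria are offered: `fraction_of_asymptote` (the
#' default) returns the smallest `t` with `B(t) >= q * b0`, found by
#' bisection to 0.01-day tolerance; `peak_daily_rate` returns the time
#' of maximum daily production (the inflection of the Gompertz curve).
#'
#' @param x A [batch_kinetics_params()], or a batch series data frame
#'   (which is first fitted with [fit_kinetics()]).
#' @param criterion `"fraction_of_asymptote"` or `"peak_daily_rate"`.
#' @param q Completion fraction in (0, 1); default 0.95.
#' @param temperature Optional operating temperature; when given, the
#'   rate parameter is first scaled by [temperature_factor()]. A
#'   temperature with zero multiplier gives `Inf` (production never
#'   starts).
#' @param tr A [temperature_response()], used with `temperature`.
#' @param model Passed to [fit_kinetics()] when `x` is a series.
#' @return HRT in days.
#' @export
#' @examples
#' p <- batch_kinetics_params(100, k = 0.1, model = "first_order")
#' optimal_hrt(p)  # ln(20)/0.1 = 29.96 days
optimal_hrt <- function(x, criterion = c("fraction_of_asymptote",
                                         "peak_daily_rate"),
                        q = 0.95, temperature = NULL,
                        tr = temperature_response(),
                        model = c("gompertz", "first_order")) {
  criterion <- match.arg(criterion)
  if (is.data.frame(x)) x <- fit_kinetics(x, model = match.arg(model))
  stopifnot(inherits(x, "batch_kinetics_params"))
  p <- x
  if (!is.null(temperature)) {
    f <- temperature_factor(temperature, tr)
    if (f == 0) return(Inf)
    if (p$model == "gompertz") p$rmax <- p$rmax * f else p$k <- p$k * f
  }
  if (criterion == "fraction_of_asymptote") {
    if (q <= 0 || q >= 1) stop("q must lie in (0, 1)", call. = FALSE)
    target <- q * p$b0
    upper <- max(p$lag, 1)
    while (cumulative_production(p, upper) < target) {
      upper <- upper * 2
      if (upper > 1e7) return(Inf)
    }
    lo <- 0; hi <- upper
    while (hi - lo > 0.01) {
      mid <- (lo + hi) / 2
      if (cumulative_production(p, mid) >= target) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  } else {
    if (p$model == "first_order") return(0)  # rate is maximal at t = 0
    stats::optimize(function(t) .production_rate(p, t),
                    interval = c(0, p$lag + 10 * p$b0 / p$rmax),
                    maximum = TRUE)$maximum
  }
}
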