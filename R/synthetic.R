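# Synthetic feedstock tables and triplicate batch-optimization
# experiments: the statistical structure the pipeline assumes, with a
# known ground truth for testing parameter recovery.

# Table templates for the characterized sludge (element/component, %).
.template_ultimate <- data.frame(
  element = c("C", "N", "H", "S", "O"),
  percent = c(45.19, 3.579, 7.299, 0.94, 42.992),
  stringsAsFactors = FALSE
)
.template_proximate <- data.frame(
  component = c("moisture", "volatile_solid", "ash", "fixed_carbon", "sulfur"),
  percent = c(6.3, 60.1, 27.0, 6.7, 0.9),
  stringsAsFactors = FALSE
)

#' Design of a batch optimization experiment
#'
#' The factorial layout of a single-fed batch digestion study: initial
#' pH, substrate-to-water loading ratio and incubation temperature are
#' varied with replicated 500 mL reactors, and cumulative biogas is
#' read on a weekly grid over the retention time.
#'
#' @param ph_levels Initial pH levels (default 5.5-9.5 in unit steps).
#' @param loading_ratios Substrate:water ratios as strings (default
#'   `"1:3"` to `"1:6"`).
#' @param temperatures_c Incubation temperatures in degC (default
#'   25/35/45: psychrophilic, mesophilic, thermophilic).
#' @param replicates Reactors per condition (default 3, triplicate).
#' @param sampling_days Observation days; default a 7-day grid over a
#'   30-day retention time plus the endpoint, extensible to 48 days.
#' @param noise_sd_frac Measurement noise standard deviation as a
#'   fraction of the condition's ultimate yield (default 0.02).
#' @param seed RNG seed for reproducible generation.
#' @return Object of class `experiment_design`.
#' @export
experiment_design <- function(ph_levels = c(5.5, 6.5, 7.5, 8.5, 9.5),
                              loading_ratios = c("1:3", "1:4", "1:5", "1:6"),
                              temperatures_c = c(25, 35, 45),
                              replicates = 3,
                              sampling_days = c(0, 7, 14, 21, 28, 30),
                              noise_sd_frac = 0.02,
                              seed = 1L) {
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (noise_sd_frac < 0) stop("noise_sd_frac must be >= 0", call. = FALSE)
  if (is.unsorted(sampling_days, strictly = TRUE)) {
    stop("sampling_days must be strictly increasing", call. = FALSE)
  }
  vapply(loading_ratios, .parse_loading_ratio, numeric(1))  # validates
  structure(
    list(ph_levels = ph_levels, loading_ratios = loading_ratios,
         temperatures_c = temperatures_c, replicates = replicates,
         sampling_days = sampling_days, noise_sd_frac = noise_sd_frac,
         seed = as.integer(seed)),
    class = "experiment_design"
  )
}

# "1:3" (substrate:water) -> substrate volume fraction 1/(1+3)
.parse_loading_ratio <- function(ratio) {
  parts <- suppressWarnings(as.numeric(strsplit(ratio, ":", fixed = TRUE)[[1]]))
  if (length(parts) != 2 || any(!is.finite(parts)) || any(parts <= 0)) {
    stop("loading ratio must look like '1:3' with positive parts",
         call. = FALSE)
  }
  parts[1] / (parts[1] + parts[2])
}

#' Response surface of the batch experiment
#'
#' The condition-dependent ground truth used by [generate_study()]:
#' the base kinetic parameters are scaled by the product of three
#' multipliers, each equal to 1 at its optimum and in \[0, 1\]
#' elsewhere — a Gaussian bump in pH, a power law in substrate fraction
#' for the loading ratio, and the CTMI temperature factor.
#'
#' @param ph_opt Optimal initial pH (default 8.5).
#' @param ph_width Gaussian width of the pH response (pH units,
#'   default 1.5).
#' @param loading_opt Optimal loading ratio (default `"1:3"`, the
#'   densest feed in the design).
#' @param loading_slope Exponent of the loading response (default 1:
#'   yield proportional to substrate fraction).
#' @param temperature A [temperature_response()].
#' @param base_params [batch_kinetics_params()] at the optimum of all
#'   three factors. The defaults (b0 = 100 volume units, rmax = 7.3
#'   per day, lag = 5 days) put the 95%-completion retention time near
#'   25 days at the optimal temperature.
#' @param methane_fraction_mean Mean methane fraction of the generated
#'   observations (default 0.41).
#' @return Object of class `response_surface`.
#' @export
response_surface <- function(ph_opt = 8.5, ph_width = 1.5,
                             loading_opt = "1:3", loading_slope = 1,
                             temperature = temperature_response(),
                             base_params = batch_kinetics_params(
                               b0 = 100, rmax = 7.3, lag = 5),
                             methane_fraction_mean = 0.41) {
  stopifnot(inherits(temperature, "temperature_response"),
            inherits(base_params, "batch_kinetics_params"))
  if (ph_width <= 0) stop("ph_width must be positive", call. = FALSE)
  structure(
    list(ph_opt = ph_opt, ph_width = ph_width, loading_opt = loading_opt,
         loading_slope = loading_slope, temperature = temperature,
         base_params = base_params,
         methane_fraction_mean = methane_fraction_mean),
    class = "response_surface"
  )
}

.ph_multiplier <- function(ph, surface) {
  exp(-(ph - surface$ph_opt)^2 / (2 * surface$ph_width^2))
}

.loading_multiplier <- function(ratio, surface) {
  frac <- .parse_loading_ratio(ratio)
  frac_opt <- .parse_loading_ratio(surface$loading_opt)
  pmin(1, (frac / frac_opt)^surface$loading_slope)
}

.condition_multiplier <- function(ph, ratio, temp, surface) {
  .ph_multiplier(ph, surface) * .loading_multiplier(ratio, surface) *
    temperature_factor(temp, surface$temperature)
}

#' Generate synthetic feedstock characterization tables
#'
#' Emulates replicate ultimate/proximate assays of the sludge by
#' multiplicative jitter of a characterized template, renormalized so
#' each synthetic sample closes like the template does.
#'
#' @param seed RNG seed.
#' @param n_samples Number of synthetic samples.
#' @param jitter_frac Relative jitter (sd of the multiplicative
#'   perturbation), in \[0, 0.2\]. 0 reproduces the template exactly.
#' @return List with data frames `ultimate` (`sample`, `element`,
#'   `percent`) and `proximate` (`sample`, `component`, `percent`).
#' @export
#' @examples
#' generate_feedstock_table(seed = 7, n_samples = 2, jitter_frac = 0.05)
generate_feedstock_table <- function(seed = 1L, n_samples = 1,
                                     jitter_frac = 0) {
  if (jitter_frac < 0 || jitter_frac > 0.2) {
    stop("jitter_frac must lie in [0, 0.2]", call. = FALSE)
  }
  set.seed(as.integer(seed))
  jitter_one <- function(pct, closure_to) {
    p <- pct * pmax(0.1, 1 + jitter_frac * stats::rnorm(length(pct)))
    p * closure_to / sum(p)
  }
  ult <- do.call(rbind, lapply(seq_len(n_samples), function(i) {
    data.frame(sample = i, element = .template_ultimate$element,
               percent = jitter_one(.template_ultimate$percent,
                                    sum(.template_ultimate$percent)),
               stringsAsFactors = FALSE)
  }))
  prox <- do.call(rbind, lapply(seq_len(n_samples), function(i) {
    main <- .template_proximate$component != "sulfur"
    pct <- .template_proximate$percent
    out <- pct
    out[main] <- jitter_one(pct[main], sum(pct[main]))
    out[!main] <- pct[!main] * pmax(0.1, 1 + jitter_frac * stats::rnorm(1))
    data.frame(sample = i, component = .template_proximate$component,
               percent = out, stringsAsFactors = FALSE)
  }))
  list(ultimate = ult, proximate = prox)
}

#' Generate a synthetic batch optimization study
#'
#' For every combination of pH, loading ratio and temperature in the
#' design, and each replicate reactor, draws a noisy cumulative biogas
#' series around the response-surface truth: the base Gompertz `b0` and
#' `rmax` are scaled by the condition multiplier, Gaussian measurement
#' noise (sd = `noise_sd_frac` x the condition's `b0`) is added, and
#' each record is floored at the previous one so cumulative volumes
#' never decrease. Per-observation methane fractions are drawn around
#' the surface mean. Conditions with a zero temperature multiplier
#' yield identically zero series.
#'
#' @param design An [experiment_design()].
#' @param surface A [response_surface()].
#' @return A data frame with one row per reactor and sampling day:
#'   `reactor_id`, `day`, `cumulative_biogas`, `cumulative_methane`,
#'   `methane_fraction`, `temperature_c`, `ph`, `loading_ratio`,
#'   `replicate`.
#' @seealso [truth_manifest()] for the generating parameters.
#' @export
generate_study <- function(design = experiment_design(),
                           surface = response_surface()) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(surface, "response_surface"))
  set.seed(design$seed)
  base <- surface$base_params
  days <- design$sampling_days
  rows <- list()
  for (temp in design$temperatures_c) {
    for (ph in design$ph_levels) {
      for (ratio in design$loading_ratios) {
        m <- .condition_multiplier(ph, ratio, temp, surface)
        b0 <- base$b0 * m
        for (rep_i in seq_len(design$replicates)) {
          if (m > 0) {
            truth <- gompertz_cumulative(days, b0, base$rmax * m, base$lag)
            obs <- truth + stats::rnorm(length(days),
                                        sd = design$noise_sd_frac * b0)
            obs <- cummax(pmax(obs, 0))
          } else {
            obs <- rep(0, length(days))
          }
          mf <- pmin(1, pmax(0, stats::rnorm(
            length(days), surface$methane_fraction_mean, 0.02)))
          rows[[length(rows) + 1]] <- data.frame(
            reactor_id = sprintf("pH%s_L%s_T%s_r%d", ph, ratio, temp, rep_i),
            day = days,
            cumulative_biogas = obs,
            cumulative_methane = mf * obs,
            methane_fraction = mf,
            temperature_c = temp,
            ph = ph,
            loading_ratio = ratio,
            replicate = rep_i,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Ground-truth parameters of a synthetic study
#'
#' The per-condition generating parameters of [generate_study()]
#' (deterministic: the truth does not depend on the noise seed), for
#' parameter-recovery checks and JSON manifests.
#'
#' @param design An [experiment_design()].
#' @param surface A [response_surface()].
#' @return Data frame with one row per condition: `ph`,
#'   `loading_ratio`, `temperature_c`, `multiplier`, `b0`, `rmax`,
#'   `lag`, `methane_fraction_mean`.
#' @export
truth_manifest <- function(design = experiment_design(),
                           surface = response_surface()) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(surface, "response_surface"))
  grid <- expand.grid(ph = design$ph_levels,
                      loading_ratio = design$loading_ratios,
                      temperature_c = design$temperatures_c,
                      stringsAsFactors = FALSE)
  base <- surface$base_params
  grid$multiplier <- mapply(function(ph, ratio, temp) {
    .condition_multiplier(ph, ratio, temp, surface)
  }, grid$ph, grid$loading_ratio, grid$temperature_c)
  grid$b0 <- base$b0 * grid$multiplier
  grid$rmax <- base$rmax * grid$multiplier
  grid$lag <- base$lag
  grid$methane_fraction_mean <- surface$methane_fraction_mean
  grid
}
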