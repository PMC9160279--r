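# Buswell-Boyle stoichiometry: complete anaerobic conversion of
# CaHbOcNdSe with water to CH4, CO2, NH3 and H2S.

#' Buswell-Boyle reaction coefficients for a feedstock formula
#'
#' Balances the anaerobic digestion reaction
#' \deqn{C_aH_bO_cN_dS_e + w\,H_2O \rightarrow n_{CH_4}\,CH_4 +
#'   n_{CO_2}\,CO_2 + d\,NH_3 + e\,H_2S}
#' assuming the reaction goes to completion and the only products are
#' the four gases (Boyle's extension of the Buswell equation to
#' nitrogen and sulfur).
#'
#' @param f An [elemental_formula()].
#' @return An object of class `boyle_stoichiometry`: a list with
#'   `water_coeff`, `ch4_coeff`, `co2_coeff`, `nh3_coeff`, `h2s_coeff`
#'   (moles per basis mass of feedstock), the mole-fraction vector
#'   `gas_fractions` over CH4/CO2/NH3/H2S, and the input `formula`.
#' @details Closed forms:
#'   \deqn{w = a - b/4 - c/2 + 3d/4 + e/2}
#'   \deqn{n_{CH_4} = a/2 + b/8 - c/4 - 3d/8 - e/4}
#'   \deqn{n_{CO_2} = a/2 - b/8 + c/4 + 3d/8 + e/4}
#'   Element balances (C, H, O, N, S) are verified on every call; a
#'   negative methane or carbon dioxide coefficient means the formula is
#'   too oxidized or too reduced for the model and raises an error of
#'   class `biogasim_infeasible_feedstock`.
#' @seealso [gas_composition()], [theoretical_methane_yield()]
#' @export
#' @examples
#' boyle_coefficients(elemental_formula(6, 12, 6))  # glucose: 3 CH4 + 3 CO2
boyle_coefficients <- function(f) {
  stopifnot(inherits(f, "elemental_formula"))
  a <- f$a; b <- f$b; c <- f$c; d <- f$d; e <- f$e
  water <- a - b / 4 - c / 2 + 3 * d / 4 + e / 2
  ch4 <- a / 2 + b / 8 - c / 4 - 3 * d / 8 - e / 4
  co2 <- a / 2 - b / 8 + c / 4 + 3 * d / 8 + e / 4
  if (ch4 < 0 || co2 < 0) {
    stop(structure(
      class = c("biogasim_infeasible_feedstock", "error", "condition"),
      list(message = sprintf(
        paste0("infeasible feedstock: CH4 coefficient %.4g, CO2 coefficient ",
               "%.4g (formula too oxidized or too reduced for the model)"),
        ch4, co2
      ), call = NULL)
    ))
  }
  # algebraic conservation checks (should hold to rounding error)
  stopifnot(
    abs(ch4 + co2 - a) < 1e-9 * max(1, a),
    abs(4 * ch4 + 3 * d + 2 * e - (b + 2 * water)) < 1e-9 * max(1, b),
    abs(2 * co2 - (c + water)) < 1e-9 * max(1, c)
  )
  gases <- c(CH4 = ch4, CO2 = co2, NH3 = d, H2S = e)
  total <- sum(gases)
  if (total <= 0) {
    stop("undefined gas composition: all product coefficients are zero",
         call. = FALSE)
  }
  structure(
    list(
      water_coeff = water, ch4_coeff = ch4, co2_coeff = co2,
      nh3_coeff = d, h2s_coeff = e,
      gas_fractions = gases / total,
      formula = f
    ),
    class = "boyle_stoichiometry"
  )
}

#' @export
print.boyle_stoichiometry <- function(x, ...) {
  cat("Buswell-Boyle stoichiometry (moles per basis mass)\n")
  cat(sprintf("  H2O %+.4g | CH4 %.4g  CO2 %.4g  NH3 %.4g  H2S %.4g\n",
              x$water_coeff, x$ch4_coeff, x$co2_coeff, x$nh3_coeff,
              x$h2s_coeff))
  fr <- x$gas_fractions
  cat(sprintf("  biogas: %.1f%% CH4, %.1f%% CO2, %.2f%% NH3, %.2f%% H2S\n",
              100 * fr[["CH4"]], 100 * fr[["CO2"]], 100 * fr[["NH3"]],
              100 * fr[["H2S"]]))
  invisible(x)
}

#' Predicted biogas composition
#'
#' Normalizes the Boyle product coefficients to mole fractions, either
#' over the full CH4/CO2/NH3/H2S mixture or over the two major gases
#' only (the convention used when biogas is quoted as "x% methane").
#'
#' @param s A `boyle_stoichiometry` result.
#' @param include_trace Include NH3 and H2S in the normalization
#'   (default `TRUE`)?
#' @return Named numeric vector of mole fractions summing to 1.
#' @export
gas_composition <- function(s, include_trace = TRUE) {
  stopifnot(inherits(s, "boyle_stoichiometry"))
  gases <- if (include_trace) {
    c(CH4 = s$ch4_coeff, CO2 = s$co2_coeff, NH3 = s$nh3_coeff,
      H2S = s$h2s_coeff)
  } else {
    c(CH4 = s$ch4_coeff, CO2 = s$co2_coeff)
  }
  total <- sum(gases)
  if (total <= 0) {
    stop("undefined gas composition: all product coefficients are zero",
         call. = FALSE)
  }
  gases / total
}

#' Theoretical methane yield of a feedstock
#'
#' Converts the stoichiometric methane coefficient into a volume of
#' methane per kilogram of feedstock, the theoretical biochemical
#' methane potential of the model (complete conversion, no
#' biodegradability correction).
#'
#' @param f An [elemental_formula()].
#' @param molar_volume Molar gas volume in L/mol; default 22.414 (ideal
#'   gas at 0 degC, 1 atm).
#' @param vs_frac Optional volatile-solid fraction of the basis mass;
#'   when given, the yield is additionally reported per kg of volatile
#'   solids (see [vs_fraction()]).
#' @return Named numeric vector: `per_kg` (L CH4 per kg of basis mass)
#'   and, if `vs_frac` is supplied, `per_kg_vs`.
#' @export
#' @examples
#' theoretical_methane_yield(elemental_formula(6, 12, 6))  # ~373 L/kg glucose
theoretical_methane_yield <- function(f, molar_volume = 22.414,
                                      vs_frac = NULL) {
  stopifnot(inherits(f, "elemental_formula"))
  if (!is.finite(molar_volume) || molar_volume <= 0) {
    stop("molar_volume must be positive (L/mol)", call. = FALSE)
  }
  s <- boyle_coefficients(f)
  per_kg <- s$ch4_coeff * molar_volume / (f$basis_mass / 1000)
  out <- c(per_kg = per_kg)
  if (!is.null(vs_frac)) {
    if (vs_frac <= 0 || vs_frac > 1) {
      stop("vs_frac must be a fraction in (0, 1]", call. = FALSE)
    }
    out <- c(out, per_kg_vs = per_kg / vs_frac)
  }
  out
}
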