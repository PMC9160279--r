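# Heating values from elemental composition: Dulong correlation and the
# HHV/LHV relation through the latent heat of the combustion water.

#' Dulong higher heating value
#'
#' Empirical HHV correlation from the dry-basis mass fractions of
#' carbon, hydrogen, oxygen and sulfur:
#' \deqn{HHV\;(kJ/kg) = 33801\,C + 144158\,(H - 0.125\,O) + 9413\,S}
#' The `H - O/8` term is the "available hydrogen" not already bound to
#' oxygen and may be negative for highly oxygenated fuels.
#'
#' @param x An [ultimate_analysis()], or `NULL` if fractions are given
#'   directly.
#' @param c_frac,h_frac,o_frac,s_frac Mass fractions, used when `x` is
#'   `NULL`.
#' @return HHV in kJ/kg.
#' @seealso [hhv_to_lhv()]
#' @export
#' @examples
#' dulong_hhv(c_frac = 1, h_frac = 0, o_frac = 0)  # 33801 kJ/kg
dulong_hhv <- function(x = NULL, c_frac = NULL, h_frac = NULL, o_frac = NULL,
                       s_frac = 0) {
  if (inherits(x, "ultimate_analysis")) {
    c_frac <- x$c_frac; h_frac <- x$h_frac
    o_frac <- x$o_frac; s_frac <- x$s_frac
  } else if (!is.null(x)) {
    stop("x must be an ultimate_analysis (or NULL with fractions supplied)",
         call. = FALSE)
  }
  v <- c(c_frac, h_frac, o_frac, s_frac)
  if (length(v) != 4 || any(!is.finite(v))) {
    stop("c_frac, h_frac, o_frac and s_frac must be finite mass fractions",
         call. = FALSE)
  }
  33801 * c_frac + 144158 * (h_frac - 0.125 * o_frac) + 9413 * s_frac
}

#' Latent heat of vaporization of water per unit mass
#'
#' Converts the molar latent heat of water at 25 degC (44.013 kJ/mol)
#' to a mass basis. With the standard molar mass 18.015 g/mol this is
#' 2.4431 MJ/kg; the value 2.445 MJ/kg often quoted in the waste-to-
#' energy literature corresponds to a rounded molar mass of 18.0 g/mol.
#'
#' @param molar_kj Molar latent heat in kJ/mol (default 44.013).
#' @param molar_mass Water molar mass in g/mol (default 18.015).
#' @return Latent heat in MJ/kg.
#' @export
#' @examples
#' water_latent_heat()                    # 2.4431 MJ/kg
#' water_latent_heat(molar_mass = 18.0)   # 2.445 MJ/kg (rounded convention)
water_latent_heat <- function(molar_kj = 44.013, molar_mass = 18.015) {
  if (molar_kj <= 0 || molar_mass <= 0) {
    stop("molar latent heat and molar mass must be positive", call. = FALSE)
  }
  molar_kj / molar_mass
}

#' Convert a higher heating value to a lower heating value
#'
#' `HHV = LHV + n * dHv`: the two heating values differ by the latent
#' heat of the water leaving the combustion as vapour. Each kg of fuel
#' produces `h_frac * 18.015/2.016` kg of water from its hydrogen
#' (2 H -> H2O), plus, optionally, its free moisture.
#'
#' @param hhv Higher heating value, kJ/kg.
#' @param h_frac Hydrogen mass fraction of the fuel.
#' @param moisture_frac Free-moisture mass fraction evaporated during
#'   combustion; 0 by default so only combustion-formed water counts.
#' @param dhv Latent heat of vaporization in MJ/kg of water; default
#'   2.445, the rounded-molar-mass convention (see
#'   [water_latent_heat()]).
#' @return An object of class `energy_values`: list with `hhv`, `lhv`
#'   (kJ/kg), `water_mass_per_kg` (kg water per kg fuel), `dhv_mass`
#'   (MJ/kg) and a logical `degenerate` flag set when the computed LHV
#'   is negative.
#' @details The identity
#'   `hhv - lhv == water_mass_per_kg * dhv_mass * 1000` holds by
#'   construction (to floating-point rounding).
#' @export
#' @examples
#' hhv_to_lhv(18138, h_frac = 0.07299)
hhv_to_lhv <- function(hhv, h_frac, moisture_frac = 0, dhv = 2.445) {
  v <- c(h_frac, moisture_frac)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
    stop("h_frac and moisture_frac must be fractions in [0, 1]", call. = FALSE)
  }
  if (!is.finite(hhv)) stop("hhv must be a finite number (kJ/kg)",
                            call. = FALSE)
  water <- h_frac * (18.015 / 2.016) + moisture_frac
  lhv <- hhv - water * dhv * 1000
  degenerate <- lhv < 0
  if (degenerate) {
    warning("computed LHV is negative; fuel is degenerate", call. = FALSE)
  }
  structure(
    list(hhv = hhv, lhv = lhv, water_mass_per_kg = water, dhv_mass = dhv,
         degenerate = degenerate),
    class = "energy_values"
  )
}

#' @export
print.energy_values <- function(x, ...) {
  cat(sprintf("HHV %.0f kJ/kg, LHV %.0f kJ/kg (%.3f kg H2O/kg fuel x %.3f MJ/kg)\n",
              x$hhv, x$lhv, x$water_mass_per_kg, x$dhv_mass))
  if (isTRUE(x$degenerate)) cat("  warning: negative LHV (degenerate fuel)\n")
  invisible(x)
}

#' Convert between energy-density units
#'
#' Calorific values are variously reported in cal/g, kJ/kg and MJ/kg;
#' this converts between them using the thermochemical calorie
#' (1 cal = 4.184 J).
#'
#' @param value Numeric value(s) to convert.
#' @param from,to Units, one of `"cal/g"`, `"kJ/kg"`, `"MJ/kg"`.
#' @return Converted value(s).
#' @export
#' @examples
#' convert_energy(5042.2, "cal/g", "kJ/kg")  # 21096.6
convert_energy <- function(value, from, to) {
  to_kj <- c("cal/g" = 4.184, "kJ/kg" = 1, "MJ/kg" = 1000)
  if (!from %in% names(to_kj) || !to %in% names(to_kj)) {
    stop("units must be one of: ", paste(names(to_kj), collapse = ", "),
         call. = FALSE)
  }
  value * to_kj[[from]] / to_kj[[to]]
}
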