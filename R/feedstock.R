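# Ultimate/proximate characterization of a digestion feedstock and its
# conversion to an empirical C-H-O-N-S molecular formula.

# IUPAC 2021 atomic weights, 4-decimal, fixed for reproducibility.
.atomic_weights <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007, S = 32.06)

.elements <- c("C", "H", "N", "S", "O")

#' Ultimate (elemental) analysis of a feedstock
#'
#' Holds the dry-basis mass fractions of carbon, hydrogen, nitrogen,
#' sulfur and oxygen that drive both the Buswell-Boyle stoichiometry and
#' the Dulong heating-value correlation.
#'
#' @param c_frac,h_frac,n_frac,s_frac,o_frac Mass fractions (0-1) of C,
#'   H, N, S and O on the chosen dry basis.
#' @param basis Either `"dry"` or `"dry-ash-free"`; a label recording how
#'   the composition was normalized. An elemental table that sums to
#'   100% with no ash term is naturally read as dry-ash-free when the
#'   proximate analysis reports appreciable ash.
#'
#' @return An object of class `ultimate_analysis`: a list with the five
#'   fractions and the basis label.
#'
#' @details The five fractions must each lie in \[0, 1\], carbon must be
#'   positive, and their sum must lie in \[0.95, 1\] (a small analytic
#'   closure error is tolerated; elemental analyses rarely close
#'   exactly).
#'
#' @seealso [load_ultimate_analysis()], [to_empirical_formula()],
#'   [dulong_hhv()]
#' @export
#' @examples
#' ua <- ultimate_analysis(0.4519, 0.07299, 0.03579, 0.0094, 0.42992)
#' ua
ultimate_analysis <- function(c_frac, h_frac, n_frac, s_frac, o_frac,
                              basis = c("dry", "dry-ash-free")) {
  basis <- match.arg(basis)
  fr <- c(C = c_frac, H = h_frac, N = n_frac, S = s_frac, O = o_frac)
  if (any(!is.finite(fr))) {
    stop("ultimate analysis fractions must be finite numbers", call. = FALSE)
  }
  if (any(fr < 0) || any(fr > 1)) {
    stop("each mass fraction must lie in [0, 1]", call. = FALSE)
  }
  if (c_frac <= 0) {
    stop("carbon fraction must be positive", call. = FALSE)
  }
  total <- sum(fr)
  if (total < 0.95 - 1e-9 || total > 1 + 1e-9) {
    stop(sprintf(
      "elemental fractions sum to %.4f; closure requires [0.95, 1]", total
    ), call. = FALSE)
  }
  structure(
    list(c_frac = c_frac, h_frac = h_frac, n_frac = n_frac,
         s_frac = s_frac, o_frac = o_frac, basis = basis),
    class = "ultimate_analysis"
  )
}

#' @export
print.ultimate_analysis <- function(x, ...) {
  cat("Ultimate analysis (", x$basis, " basis)\n", sep = "")
  v <- c(C = x$c_frac, H = x$h_frac, N = x$n_frac, S = x$s_frac, O = x$o_frac)
  for (el in names(v)) cat(sprintf("  %s: %7.3f %%\n", el, 100 * v[[el]]))
  cat(sprintf("  sum: %.3f %%\n", 100 * sum(v)))
  invisible(x)
}

#' Read an ultimate analysis from a table
#'
#' Parses a delimited table (or in-memory data frame) with columns
#' `element` and `percent`, one row per element among C, H, N, S, O, and
#' returns a validated [ultimate_analysis()].
#'
#' @param x Path to a CSV file, or a data frame with columns `element`
#'   and `percent`.
#' @param basis Basis label passed to [ultimate_analysis()].
#' @param strict If `TRUE`, every one of the five elements must be
#'   present; the error names the first missing element. The default
#'   treats absent elements as 0%, so e.g. a pure-carbon record is
#'   accepted.
#'
#' @return An `ultimate_analysis` object (fractions = percent / 100).
#' @export
#' @examples
#' path <- system.file("extdata", "sludge_ultimate.csv", package = "biogasim")
#' load_ultimate_analysis(path)
load_ultimate_analysis <- function(x, basis = c("dry", "dry-ash-free"),
                                   strict = FALSE) {
  tab <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE) else x
  if (!all(c("element", "percent") %in% names(tab))) {
    stop("ultimate analysis table needs columns 'element' and 'percent'",
         call. = FALSE)
  }
  tab$element <- toupper(trimws(as.character(tab$element)))
  unknown <- setdiff(tab$element, .elements)
  if (length(unknown)) {
    stop("unknown element row(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tab$element)) {
    stop("duplicated element rows in ultimate analysis table", call. = FALSE)
  }
  missing <- setdiff(.elements, tab$element)
  if (strict && length(missing)) {
    stop("missing element row: ", missing[1], call. = FALSE)
  }
  bad <- tab$element[!is.finite(suppressWarnings(as.numeric(tab$percent)))]
  if (length(bad)) {
    stop("non-numeric percent for element: ", bad[1], call. = FALSE)
  }
  pct <- stats::setNames(rep(0, 5), .elements)
  pct[tab$element] <- as.numeric(tab$percent)
  total <- sum(pct)
  if (total < 95 || total > 100 + 1e-9) {
    stop(sprintf(
      "element percentages sum to %.2f%%; expected closure within [95, 100]%%",
      total
    ), call. = FALSE)
  }
  ultimate_analysis(pct[["C"]] / 100, pct[["H"]] / 100, pct[["N"]] / 100,
                    pct[["S"]] / 100, pct[["O"]] / 100, basis = basis)
}

#' Proximate analysis of a feedstock
#'
#' Moisture, volatile solids, ash, fixed carbon and sulfur as the
#' percentages a proximate assay prints (moisture of wet mass, the rest
#' of dry mass).
#'
#' @param moisture,volatile_solid,ash,fixed_carbon,sulfur Percentages
#'   (0-100).
#' @return An object of class `proximate_analysis`.
#' @details `moisture + volatile_solid + ash + fixed_carbon` must fall
#'   in \[95, 105\]; published proximate tables often do not close to
#'   exactly 100.
#' @seealso [load_proximate_analysis()], [vs_fraction()]
#' @export
proximate_analysis <- function(moisture, volatile_solid, ash, fixed_carbon,
                               sulfur = 0) {
  v <- c(moisture = moisture, volatile_solid = volatile_solid, ash = ash,
         fixed_carbon = fixed_carbon, sulfur = sulfur)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 100)) {
    stop("proximate components must be percentages in [0, 100]", call. = FALSE)
  }
  closure <- moisture + volatile_solid + ash + fixed_carbon
  if (closure < 95 || closure > 105) {
    stop(sprintf(
      "moisture + VS + ash + fixed carbon = %.1f%%; expected within [95, 105]",
      closure
    ), call. = FALSE)
  }
  structure(as.list(v), class = "proximate_analysis")
}

#' @export
print.proximate_analysis <- function(x, ...) {
  cat("Proximate analysis\n")
  for (nm in names(x)) cat(sprintf("  %-14s %6.2f %%\n", nm, x[[nm]]))
  invisible(x)
}

#' Read a proximate analysis from a table
#'
#' @param x Path to a CSV with columns `component` and `percent`, or an
#'   equivalent data frame. Recognised components: `moisture`,
#'   `volatile_solid`, `ash`, `fixed_carbon`, `sulfur`.
#' @return A `proximate_analysis` object.
#' @export
load_proximate_analysis <- function(x) {
  tab <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE) else x
  if (!all(c("component", "percent") %in% names(tab))) {
    stop("proximate table needs columns 'component' and 'percent'",
         call. = FALSE)
  }
  comp <- gsub("[ -]", "_", tolower(trimws(tab$component)))
  known <- c("moisture", "volatile_solid", "ash", "fixed_carbon", "sulfur")
  unknown <- setdiff(comp, known)
  if (length(unknown)) {
    stop("unknown proximate component(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  pct <- stats::setNames(rep(0, length(known)), known)
  pct[comp] <- as.numeric(tab$percent)
  proximate_analysis(pct[["moisture"]], pct[["volatile_solid"]], pct[["ash"]],
                     pct[["fixed_carbon"]], pct[["sulfur"]])
}

#' Volatile-solid fraction of a feedstock
#'
#' Theoretical yields are conventionally normalized either per dry mass
#' or per mass of volatile solids (the biodegradable part). This helper
#' returns VS as a fraction of total (wet) or dry mass.
#'
#' @param pa A [proximate_analysis()].
#' @param basis `"wet"` (as printed) or `"dry"` (VS / (100 - moisture)).
#' @return A fraction in (0, 1].
#' @export
vs_fraction <- function(pa, basis = c("dry", "wet")) {
  stopifnot(inherits(pa, "proximate_analysis"))
  basis <- match.arg(basis)
  switch(basis,
    wet = pa$volatile_solid / 100,
    dry = pa$volatile_solid / (100 - pa$moisture)
  )
}

#' Empirical molecular formula CaHbOcNdSe of a feedstock
#'
#' Converts the elemental mass fractions of an ultimate analysis into
#' moles of C, H, O, N and S contained in a chosen basis mass, i.e. the
#' subscripts of the empirical formula the digestion stoichiometry
#' operates on.
#'
#' @param ua An [ultimate_analysis()].
#' @param basis_mass Basis mass in grams (default 100 g, so moles are
#'   per 100 g of feedstock).
#' @return An object of class `elemental_formula` with fields `a`, `b`,
#'   `c`, `d`, `e` (moles of C, H, O, N, S) and `basis_mass`.
#' @details Moles are mass fraction x basis mass / atomic weight, with
#'   atomic weights C 12.011, H 1.008, O 15.999, N 14.007, S 32.06.
#'   The conversion is exactly linear in `basis_mass`.
#' @seealso [boyle_coefficients()], [formula_mass_fractions()]
#' @export
#' @examples
#' ua <- ultimate_analysis(0.4519, 0.07299, 0.03579, 0.0094, 0.42992)
#' to_empirical_formula(ua, basis_mass = 100)
to_empirical_formula <- function(ua, basis_mass = 100) {
  stopifnot(inherits(ua, "ultimate_analysis"))
  if (!is.finite(basis_mass) || basis_mass <= 0) {
    stop("basis_mass must be a positive mass in grams", call. = FALSE)
  }
  w <- .atomic_weights
  f <- structure(
    list(
      # grouped as basis_mass * (frac / weight) so scaling the basis
      # mass rescales the moles bit-exactly
      a = basis_mass * (ua$c_frac / w[["C"]]),
      b = basis_mass * (ua$h_frac / w[["H"]]),
      c = basis_mass * (ua$o_frac / w[["O"]]),
      d = basis_mass * (ua$n_frac / w[["N"]]),
      e = basis_mass * (ua$s_frac / w[["S"]]),
      basis_mass = basis_mass
    ),
    class = "elemental_formula"
  )
  # mass reconstruction must agree with the analysed mass to 0.1%
  mass_in <- basis_mass * (ua$c_frac + ua$h_frac + ua$o_frac + ua$n_frac +
                             ua$s_frac)
  mass_back <- f$a * w[["C"]] + f$b * w[["H"]] + f$c * w[["O"]] +
    f$d * w[["N"]] + f$e * w[["S"]]
  if (abs(mass_back - mass_in) > 1e-3 * mass_in) {
    stop("internal error: formula does not reconstruct the input mass",
         call. = FALSE)
  }
  f
}

#' Construct an elemental formula directly from molar subscripts
#'
#' @param a,b,c,d,e Moles of C, H, O, N, S per basis mass. All must be
#'   non-negative and `a` positive.
#' @param basis_mass Basis mass in grams; by default the molar mass of
#'   the formula, so the object describes one mole.
#' @return An `elemental_formula` object.
#' @export
#' @examples
#' elemental_formula(6, 12, 6)  # glucose
elemental_formula <- function(a, b = 0, c = 0, d = 0, e = 0,
                              basis_mass = NULL) {
  m <- c(a, b, c, d, e)
  if (any(!is.finite(m)) || any(m < 0) || a <= 0) {
    stop("molar subscripts must be non-negative with a > 0", call. = FALSE)
  }
  w <- .atomic_weights
  molar_mass <- a * w[["C"]] + b * w[["H"]] + c * w[["O"]] + d * w[["N"]] +
    e * w[["S"]]
  if (is.null(basis_mass)) basis_mass <- molar_mass
  structure(
    list(a = a, b = b, c = c, d = d, e = e, basis_mass = basis_mass),
    class = "elemental_formula"
  )
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat(sprintf(
    "Empirical formula C%.4g H%.4g O%.4g N%.4g S%.4g per %.4g g\n",
    x$a, x$b, x$c, x$d, x$e, x$basis_mass
  ))
  invisible(x)
}

#' Mass fractions implied by an elemental formula
#'
#' Inverse of [to_empirical_formula()]: multiplies molar subscripts by
#' atomic weights and normalizes by the basis mass.
#'
#' @param f An `elemental_formula`.
#' @return Named numeric vector of mass fractions for C, H, N, S, O.
#' @export
formula_mass_fractions <- function(f) {
  stopifnot(inherits(f, "elemental_formula"))
  w <- .atomic_weights
  c(
    C = f$a * w[["C"]], H = f$b * w[["H"]], N = f$d * w[["N"]],
    S = f$e * w[["S"]], O = f$c * w[["O"]]
  ) / f$basis_mass
}
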