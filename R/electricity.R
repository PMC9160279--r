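# Electricity generation potential of biogas burned in an internal
# combustion engine: E = Q_biogas x F_CH4 x Cp_CH4 x eta_elec.

#' Electricity potential of a biogas volume
#'
#' Multiplies the biogas quantity by its methane fraction, the specific
#' energy of methane and the electrical conversion efficiency:
#' \deqn{E_{elec} = Q_{biogas} \times F_{CH_4} \times Cp_{CH_4} \times
#'   \eta_{elec}}
#'
#' @param q_biogas Biogas volume in m3 (>= 0).
#' @param f_ch4 Methane fraction of the biogas, in \[0, 1\]. A value
#'   above 1 raises an error suggesting the percent/fraction mix-up.
#' @param cp_ch4 Specific energy of methane, kWh/m3. Default 10; the
#'   Swedish Gas Centre value 9.97 is a common alternative.
#' @param eta_elec Electrical efficiency of the engine, in \[0, 1\].
#'   Default 0.30 (typical of small CHP units, which span roughly
#'   0.25-0.43).
#' @return Object of class `electricity_estimate`: the four factors,
#'   `e_elec` (kWh) and the unit label.
#' @seealso [electricity_from_methane()], [report_kwh()],
#'   [aggregate_period()]
#' @export
#' @examples
#' electricity_from_biogas(17.9, 0.616)  # 33.1 kWh at default Cp and eta
electricity_from_biogas <- function(q_biogas, f_ch4, cp_ch4 = 10,
                                    eta_elec = 0.30) {
  if (!is.finite(q_biogas) || q_biogas < 0) {
    stop("q_biogas must be a non-negative volume", call. = FALSE)
  }
  if (f_ch4 > 1 || eta_elec > 1) {
    stop(paste0("f_ch4 and eta_elec are fractions in [0, 1]; a value above 1 ",
                "suggests a percentage was passed - divide by 100"),
         call. = FALSE)
  }
  if (f_ch4 < 0 || eta_elec < 0) {
    stop("f_ch4 and eta_elec must be non-negative fractions", call. = FALSE)
  }
  if (!is.finite(cp_ch4) || cp_ch4 <= 0) {
    stop("cp_ch4 must be positive (kWh/m3)", call. = FALSE)
  }
  structure(
    list(q_biogas = q_biogas, f_ch4 = f_ch4, cp_ch4 = cp_ch4,
         eta_elec = eta_elec,
         e_elec = q_biogas * f_ch4 * cp_ch4 * eta_elec,
         unit = "kWh"),
    class = "electricity_estimate"
  )
}

#' Electricity potential of a methane volume
#'
#' Same as [electricity_from_biogas()] with the methane volume given
#' directly (methane fraction 1).
#'
#' @param v_ch4 Methane volume, m3 (>= 0).
#' @inheritParams electricity_from_biogas
#' @return An `electricity_estimate`.
#' @export
#' @examples
#' electricity_from_methane(6.3)  # 18.9 kWh
electricity_from_methane <- function(v_ch4, cp_ch4 = 10, eta_elec = 0.30) {
  electricity_from_biogas(v_ch4, 1, cp_ch4, eta_elec)
}

#' Report an electricity estimate in kWh at one decimal
#'
#' Energy balances of this kind are conventionally quoted to one
#' decimal place.
#'
#' @param x An `electricity_estimate`.
#' @return The energy in kWh rounded to one decimal.
#' @export
report_kwh <- function(x) {
  stopifnot(inherits(x, "electricity_estimate"))
  round(x$e_elec, 1)
}

#' @export
print.electricity_estimate <- function(x, ...) {
  cat(sprintf(
    "E_elec = %.4g m3 x %.3f CH4 x %.4g kWh/m3 x %.2f = %.1f %s\n",
    x$q_biogas, x$f_ch4, x$cp_ch4, x$eta_elec, x$e_elec, x$unit
  ))
  invisible(x)
}

#' Total electricity over a reporting period
#'
#' Sums a list of electricity estimates (e.g. daily values) into a
#' period total.
#'
#' @param estimates Non-empty list of `electricity_estimate` objects
#'   with a common unit.
#' @param period_label Optional label (e.g. `"month"`) attached to the
#'   result.
#' @return Total energy (kWh) with attributes `unit` and `period`.
#' @export
#' @examples
#' aggregate_period(list(electricity_from_methane(6.3),
#'                       electricity_from_biogas(4.7, 1)), "month")
aggregate_period <- function(estimates, period_label = NULL) {
  if (!is.list(estimates) || length(estimates) == 0) {
    stop("estimates must be a non-empty list", call. = FALSE)
  }
  if (!all(vapply(estimates, inherits, logical(1), "electricity_estimate"))) {
    stop("every element must be an electricity_estimate", call. = FALSE)
  }
  units <- unique(vapply(estimates, `[[`, character(1), "unit"))
  if (length(units) != 1) {
    stop("estimates mix units: ", paste(units, collapse = ", "),
         call. = FALSE)
  }
  total <- sum(vapply(estimates, `[[`, numeric(1), "e_elec"))
  structure(total, unit = units, period = period_label)
}
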