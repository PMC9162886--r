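# CEA parameter set for one device: the inputs to the value-based price
# equation. Costs stay tagged with their source currency until an explicit
# conversion; the comparator cost is kept aggregate (splitting it into
# device price + other costs is not needed when pricing the new arm).

#' Cost-effectiveness inputs for one device
#'
#' Bundles the parameters needed to compute a value-based price for a new
#' intervention A against a comparator B: the per-patient effectiveness
#' gain, the comparator's total cost `cost_B`, and the non-device costs of
#' delivering A (`othercosts_A`). When only one-year survival proportions
#' are published, the gain may be the survival difference in life-years
#' (`outcome_kind = "life_year"`); downstream results flag this proxy.
#'
#' @param gain per-patient effectiveness gain (QALYs, or life-years for the
#'   one-year survival proxy). Negative values are allowed and flagged.
#' @param cost_B total comparator cost, a [money()] amount (kept aggregate).
#' @param othercosts_A non-device costs of the new intervention, a [money()].
#' @param outcome_kind `"QALY"` or `"life_year"`.
#' @param time_horizon_months positive integer, or `"lifetime"`.
#' @param source free-text citation tag for the underlying CEA.
#' @param source_kind `"CEA_registry"` or `"HTA_report"` — the two source
#'   types accepted at screening.
#' @return an object of class `cea_inputs`.
#' @export
#' @examples
#' cea_inputs(gain = 1.07, cost_B = money(10704, "GBP"),
#'            othercosts_A = money(26471, "GBP"),
#'            time_horizon_months = "lifetime", source_kind = "HTA_report")
cea_inputs <- function(gain,
                       cost_B = money(0, "EUR"),
                       othercosts_A = money(0, "EUR"),
                       outcome_kind = c("QALY", "life_year"),
                       time_horizon_months = "lifetime",
                       source = "",
                       source_kind = c("CEA_registry", "HTA_report")) {
  outcome_kind <- match.arg(outcome_kind)
  source_kind <- match.arg(source_kind)
  if (!is.numeric(gain) || length(gain) != 1L || !is.finite(gain))
    stop_domain("gain must be a single finite number")
  if (!inherits(cost_B, "money") || !inherits(othercosts_A, "money"))
    stop_domain("cost_B and othercosts_A must be money amounts with explicit currencies")
  if (!identical(time_horizon_months, "lifetime")) {
    th <- suppressWarnings(as.numeric(time_horizon_months))
    if (is.na(th) || th <= 0 || th != round(th))
      stop_domain("time_horizon_months must be a positive integer or \"lifetime\"")
    time_horizon_months <- as.integer(th)
  }
  structure(list(gain = gain, outcome_kind = outcome_kind,
                 cost_B = cost_B, othercosts_A = othercosts_A,
                 time_horizon_months = time_horizon_months,
                 source = source, source_kind = source_kind),
            class = "cea_inputs")
}

#' @export
print.cea_inputs <- function(x, ...) {
  cat("<cea_inputs>\n")
  cat("  gain:        ", x$gain, " ", x$outcome_kind,
      if (x$outcome_kind == "life_year") " (survival proxy)", "\n", sep = "")
  cat("  cost_B:      ", format(x$cost_B), "\n")
  cat("  othercosts_A:", format(x$othercosts_A), "\n")
  cat("  horizon:     ", x$time_horizon_months, "months\n")
  if (nzchar(x$source)) cat("  source:      ", x$source, " [", x$source_kind, "]\n", sep = "")
  invisible(x)
}

#' Convert all monetary fields of CEA inputs to euro
#'
#' Returns a copy with `cost_B` and `othercosts_A` converted via
#' [to_eur()]; the effectiveness gain is untouched.
#'
#' @param inputs a [cea_inputs()] object.
#' @param rates an [exchange_rate_table()].
#' @inheritParams to_eur
#' @return a `cea_inputs` object with all amounts in EUR.
#' @export
cea_inputs_to_eur <- function(inputs, rates, digits = 6) {
  if (!inherits(inputs, "cea_inputs")) stop_domain("inputs must be cea_inputs")
  inputs$cost_B <- to_eur(inputs$cost_B, rates, digits)
  inputs$othercosts_A <- to_eur(inputs$othercosts_A, rates, digits)
  inputs
}

is_eur <- function(inputs) {
  inputs$cost_B$currency == "EUR" && inputs$othercosts_A$currency == "EUR"
}
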