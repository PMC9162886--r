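# Cost-effectiveness algebra: ICER, incremental cost, the value-based
# price at a willingness-to-pay threshold, the one-year survival gain
# proxy, cost decomposition, price bands and concordance classification.
#
# The value-based price inverts the ICER definition: with
#   ICER = (price_A + othercosts_A - cost_B) / gain
# setting ICER equal to a willingness-to-pay threshold w and solving for
# the device price gives
#   VBP_A = w * gain - othercosts_A + cost_B .

#' Willingness-to-pay threshold (EUR per QALY)
#'
#' Validates a strictly positive cost-per-QALY threshold. The package-wide
#' defaults are a primary threshold of 60,000 EUR/QALY (the highest
#' acceptable price) and a secondary of 30,000 EUR/QALY, which together
#' define a price band.
#'
#' @param value threshold in EUR per QALY gained; must be > 0.
#' @return the validated numeric value, classed `wtp_threshold`.
#' @export
wtp_threshold <- function(value) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) || value <= 0)
    stop_domain("a willingness-to-pay threshold must be a single positive number")
  structure(as.numeric(value), class = "wtp_threshold")
}

as_wtp <- function(w) if (inherits(w, "wtp_threshold")) unclass(w) else unclass(wtp_threshold(w))

money_or_eur <- function(x, what) {
  if (inherits(x, "money")) x else if (is.numeric(x)) money(x, "EUR")
  else stop_domain(sprintf("%s must be money or a numeric EUR amount", what))
}

#' Incremental cost-effectiveness ratio
#'
#' `(cost_A - cost_B) / (qalys_A - qalys_B)`, in EUR per QALY. Costs may be
#' [money()] (both in the same currency, normally EUR) or plain numerics
#' interpreted as EUR. Sign conventions are preserved: a negative ICER
#' signals dominance on one axis. Equal effectiveness in both arms makes
#' the ratio undefined and raises a classed `vbp_undefined_icer` error.
#'
#' @param cost_A,cost_B total per-patient costs of the new arm and comparator.
#' @param qalys_A,qalys_B per-patient effectiveness of each arm.
#' @return ICER in EUR per QALY (numeric).
#' @export
#' @examples
#' icer(15702, 0, 0.138, 0) # EUR per QALY for a published delta-cost
icer <- function(cost_A, cost_B, qalys_A, qalys_B) {
  cost_A <- money_or_eur(cost_A, "cost_A")
  cost_B <- money_or_eur(cost_B, "cost_B")
  check_same_currency(cost_A, cost_B)
  if (qalys_A == qalys_B)
    stop_vbp(paste0("undefined ICER: both arms yield the same effectiveness (",
                    qalys_A, "); the cheaper arm simply dominates"),
             "vbp_undefined_icer")
  (cost_A$amount - cost_B$amount) / (qalys_A - qalys_B)
}

#' Incremental cost from an ICER and a gain
#'
#' `incremental_cost = ICER x gain`: the total extra cost of the new arm
#' implied by a cost-effectiveness ratio and an effectiveness gain.
#'
#' @param icer_value EUR per QALY.
#' @param gain effectiveness gain (QALYs or life-years).
#' @return incremental cost in EUR.
#' @export
incremental_cost <- function(icer_value, gain) {
  icer_value * gain
}

#' Value-based price at a willingness-to-pay threshold
#'
#' Computes `w * gain - othercosts_A + cost_B` in EUR: the device price at
#' which the intervention's ICER exactly equals the threshold `w`. The
#' result is returned unrounded; round to whole euros only for
#' presentation (see [round_half_up()]). A negative result is returned
#' as-is with a warning — it means the device cannot be cost-effective at
#' any positive price. A gain of zero or less, or a life-year proxy gain,
#' also warns (classed `vbp_warning` conditions) without failing.
#'
#' @param wtp threshold in EUR/QALY ([wtp_threshold()] or positive number).
#' @param inputs [cea_inputs()] with all monetary fields already in EUR
#'   (convert with [cea_inputs_to_eur()] first).
#' @return the value-based price in EUR (numeric, unrounded).
#' @export
#' @examples
#' inp <- cea_inputs(gain = 0.048)
#' value_based_price(60000, inp)
value_based_price <- function(wtp, inputs) {
  w <- as_wtp(wtp)
  if (!inherits(inputs, "cea_inputs")) stop_domain("inputs must be cea_inputs")
  if (!is_eur(inputs))
    stop_currency_mismatch("EUR",
      paste(unique(c(inputs$cost_B$currency, inputs$othercosts_A$currency)), collapse = "/"))
  if (inputs$outcome_kind == "life_year")
    warn_vbp("gain is a life-year survival proxy, used with implicit utility weight 1",
             "life_year_proxy")
  if (inputs$gain <= 0)
    warn_vbp("effectiveness gain is zero or negative", "nonpositive_gain")
  vbp <- w * inputs$gain - inputs$othercosts_A$amount + inputs$cost_B$amount
  if (vbp < 0)
    warn_vbp("negative value-based price: not cost-effective at any positive price",
             "negative_vbp")
  vbp
}

#' One-year survival difference as a life-year gain
#'
#' When a CEA reports only one-year survival proportions, their difference
#' is usable as the effectiveness gain over a 12-month horizon, in
#' life-years rather than QALYs (no utility weighting, no discounting).
#'
#' @param surv_A,surv_B one-year survival proportions in \[0, 1\].
#' @return life-years gained (numeric; antisymmetric in its arguments).
#' @export
#' @examples
#' survival_gain_one_year(0.804, 0.756)
survival_gain_one_year <- function(surv_A, surv_B) {
  if (any(c(surv_A, surv_B) < 0) || any(c(surv_A, surv_B) > 1))
    stop_domain("survival proportions must lie in [0, 1]")
  surv_A - surv_B
}

#' Derive non-device costs from a published incremental cost
#'
#' Published CEAs often report only an aggregate incremental cost. The
#' non-device costs of the new intervention are then the incremental cost
#' minus the device's own price, in the shared currency. A negative result
#' is returned with a warning.
#'
#' @param delta_cost published incremental cost, a [money()] amount.
#' @param device_price the device price in the same currency.
#' @return othercosts_A as a [money()] amount.
#' @export
#' @examples
#' other_costs_from_delta(money(15702, "EUR"), money(7000, "EUR"))
other_costs_from_delta <- function(delta_cost, device_price) {
  if (!inherits(delta_cost, "money") || !inherits(device_price, "money"))
    stop_domain("delta_cost and device_price must be money amounts")
  out <- delta_cost - device_price # currency check in Ops.money
  if (out$amount < 0)
    warn_vbp("derived othercosts_A is negative", "negative_othercosts")
  out
}

#' Value-based price band between two thresholds
#'
#' The pair (VBP at the secondary threshold, VBP at the primary threshold)
#' proposes a price range for a device; the high end is the highest
#' acceptable price.
#'
#' @param inputs [cea_inputs()] in EUR.
#' @param wtp_primary,wtp_secondary thresholds in EUR/QALY, secondary <= primary.
#' @return named numeric `c(low = , high = )` in EUR.
#' @export
price_band <- function(inputs, wtp_primary = 60000, wtp_secondary = 30000) {
  wp <- as_wtp(wtp_primary); ws <- as_wtp(wtp_secondary)
  if (ws > wp)
    stop_domain("the secondary threshold must not exceed the primary threshold")
  c(low = value_based_price(ws, inputs),
    high = value_based_price(wp, inputs))
}

#' Classify concordance of a real price with its value-based price
#'
#' A device is `concordant` when the real price lies within a relative
#' band around the value-based price: `|real/vbp - 1| <= band_fraction`.
#' Above the band it is `real_above_vbp`; below, `vbp_above_real`. The
#' default band of +/-20% separates prices "very similar" to their
#' value-based level from markedly discordant ones.
#'
#' @param vbp_primary value-based price at the primary threshold, EUR, > 0.
#' @param real_price real market price, EUR, > 0.
#' @param band_fraction half-width of the relative concordance band.
#' @return one of `"concordant"`, `"real_above_vbp"`, `"vbp_above_real"`.
#' @export
#' @examples
#' classify_concordance(6578, 6500)
#' classify_concordance(2880, 13000)
classify_concordance <- function(vbp_primary, real_price, band_fraction = 0.2) {
  if (!is.finite(vbp_primary) || vbp_primary <= 0 ||
      !is.finite(real_price) || real_price <= 0)
    stop_domain("concordance requires strictly positive value-based and real prices")
  if (band_fraction < 0) stop_domain("band_fraction must be non-negative")
  rel <- real_price / vbp_primary - 1
  if (abs(rel) <= band_fraction) "concordant"
  else if (rel > 0) "real_above_vbp"
  else "vbp_above_real"
}
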