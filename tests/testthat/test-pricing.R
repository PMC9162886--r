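test_that("ICER divides incremental cost by incremental effectiveness", {
  expect_equal(icer(1000, 1000, 1.5, 1.0), 0)
  # published delta-cost over printed QALY gain, frozen by long division
  expect_equal(icer(15702, 0, 0.138, 0), 113782.608696, tolerance = 1e-9)
  # sign preserved when one arm dominates on one axis
  expect_lt(icer(500, 1000, 1.5, 1.0), 0)
  expect_error(icer(100, 50, 1.2, 1.2), class = "vbp_undefined_icer")
  expect_match(tryCatch(icer(100, 50, 1.2, 1.2), error = conditionMessage),
               "dominates")
  expect_error(icer(money(10, "EUR"), money(10, "GBP"), 1, 0),
               class = "vbp_currency_mismatch")
})

test_that("incremental cost is the ICER-gain product and inverts the ICER", {
  expect_equal(incremental_cost(60000, 0.048), 2880)
  expect_equal(incremental_cost(123456, 0), 0)
  set.seed(7)
  for (i in 1:25) {
    cA <- runif(1, 0, 1e5); cB <- runif(1, 0, 1e5)
    qA <- runif(1, 0, 5); qB <- runif(1, 0, 5)
    if (qA == qB) next
    expect_equal(incremental_cost(icer(cA, cB, qA, qB), qA - qB), cA - cB,
                 tolerance = 1e-10)
  }
})

test_that("value-based price reproduces the appraised device prices", {
  # zero-cost rows: price is threshold times gain
  expect_equal(suppressWarnings(
    value_based_price(60000, cea_inputs(0.048, outcome_kind = "life_year"))), 2880)
  expect_equal(suppressWarnings(
    value_based_price(60000, cea_inputs(0.13, outcome_kind = "life_year"))), 7800)
  expect_equal(suppressWarnings(value_based_price(60000, cea_inputs(0))), 0)
  # GBP-costed row, converted at 0.833 units per euro then priced
  rt <- fixture_rates()
  inp4 <- cea_inputs_to_eur(
    cea_inputs(1.07, cost_B = money(10704, "GBP"),
               othercosts_A = money(26471, "GBP")), rt)
  expect_equal(round_half_up(value_based_price(60000, inp4)), 45272)
  # BRL-costed row at 5.15 units per euro
  inp5 <- cea_inputs_to_eur(
    cea_inputs(0.03, cost_B = money(16000, "BRL"),
               othercosts_A = money(6836, "BRL")), rt)
  expect_equal(round_half_up(value_based_price(60000, inp5)), 3579)
})

test_that("value-based price warns on proxies, negative prices and bad gains", {
  expect_warning(value_based_price(60000, cea_inputs(0.1, outcome_kind = "life_year")),
                 class = "vbp_life_year_proxy")
  expect_warning(
    v <- value_based_price(60000, cea_inputs(0.01, othercosts_A = money(5000, "EUR"))),
    class = "vbp_negative_vbp")
  expect_equal(v, -4400) # returned as-is, not floored
  # a negative gain triggers both the gain and the negative-price flags
  expect_warning(
    expect_warning(value_based_price(60000, cea_inputs(-0.05)),
                   class = "vbp_nonpositive_gain"),
    class = "vbp_negative_vbp")
  expect_error(value_based_price(60000, cea_inputs(1, cost_B = money(1, "GBP"))),
               class = "vbp_currency_mismatch")
  expect_error(wtp_threshold(-5), class = "vbp_domain_error")
})

test_that("value-based price is affine in the threshold and monotone in inputs", {
  set.seed(11)
  for (i in 1:25) {
    inp <- random_cea_inputs()
    w <- runif(1, 1e3, 1e5)
    vbp <- function(w, inp) suppressWarnings(value_based_price(w, inp))
    v0 <- vbp(w, inp)
    # slope in w equals the gain; intercept is cost_B - othercosts_A
    expect_equal(vbp(w + 1000, inp) - v0, 1000 * inp$gain, tolerance = 1e-9)
    expect_equal(v0 - w * inp$gain,
                 inp$cost_B$amount - inp$othercosts_A$amount, tolerance = 1e-9)
    # strictly increasing in gain, increasing in cost_B, decreasing in othercosts_A
    up <- inp; up$gain <- inp$gain + 0.01
    expect_gt(vbp(w, up), v0)
    up <- inp; up$cost_B <- inp$cost_B + money(100, "EUR")
    expect_gt(vbp(w, up), v0)
    up <- inp; up$othercosts_A <- inp$othercosts_A + money(100, "EUR")
    expect_lt(vbp(w, up), v0)
  }
})

test_that("pricing at the value-based price returns exactly the threshold", {
  set.seed(23)
  for (i in 1:100) {
    inp <- random_cea_inputs()
    w <- runif(1, 1e3, 1e5)
    price_A <- suppressWarnings(value_based_price(w, inp))
    back <- icer(price_A + inp$othercosts_A$amount, inp$cost_B$amount,
                 inp$gain, 0)
    expect_equal(back, w, tolerance = 1e-9)
  }
})

test_that("one-year survival differences give antisymmetric life-year gains", {
  expect_equal(survival_gain_one_year(0.804, 0.756), 0.048)
  expect_equal(survival_gain_one_year(0.36, 0.23), 0.13)
  expect_equal(survival_gain_one_year(0.5, 0.5), 0)
  set.seed(3)
  for (i in 1:20) {
    a <- runif(1); b <- runif(1)
    expect_equal(survival_gain_one_year(a, b), -survival_gain_one_year(b, a))
  }
  expect_error(survival_gain_one_year(1.2, 0.5), class = "vbp_domain_error")
  expect_error(survival_gain_one_year(0.5, -0.1), class = "vbp_domain_error")
})

test_that("non-device costs derive from published incremental costs", {
  oc <- other_costs_from_delta(money(15702, "EUR"), money(7000, "EUR"))
  expect_equal(oc$amount, 8702)
  expect_equal(oc$currency, "EUR")
  oc2 <- other_costs_from_delta(money(19267, "R$"), money(12431, "BRL"))
  expect_equal(oc2$amount, 6836)
  expect_equal(other_costs_from_delta(money(500, "EUR"), money(500, "EUR"))$amount, 0)
  expect_warning(other_costs_from_delta(money(100, "EUR"), money(900, "EUR")),
                 class = "vbp_negative_othercosts")
  expect_error(other_costs_from_delta(money(100, "EUR"), money(50, "GBP")),
               class = "vbp_currency_mismatch")
})

test_that("price bands span the secondary-to-primary threshold range", {
  band <- suppressWarnings(
    price_band(cea_inputs(0.13, outcome_kind = "life_year"), 60000, 30000))
  expect_equal(unname(band), c(3900, 7800))
  zero <- suppressWarnings(
    price_band(cea_inputs(0, cost_B = money(500, "EUR"),
                          othercosts_A = money(500, "EUR"))))
  expect_equal(unname(zero), c(0, 0))
  same <- price_band(cea_inputs(0.1), 60000, 60000)
  expect_equal(same[["low"]], same[["high"]])
  expect_error(price_band(cea_inputs(0.1), 30000, 60000), class = "vbp_domain_error")
  # band ordering: low <= high whenever gain >= 0
  set.seed(5)
  for (i in 1:20) {
    b <- suppressWarnings(price_band(random_cea_inputs(), 60000, runif(1, 1e3, 6e4)))
    expect_lte(b[["low"]], b[["high"]])
  }
  # band difference equals threshold difference times gain
  inp <- random_cea_inputs()
  b <- suppressWarnings(price_band(inp, 60000, 30000))
  expect_equal(b[["high"]] - b[["low"]], 30000 * inp$gain, tolerance = 1e-9)
})

test_that("concordance classification uses a relative band around the VBP", {
  expect_equal(classify_concordance(6578, 6500), "concordant")
  expect_equal(classify_concordance(2880, 13000), "real_above_vbp")
  expect_equal(classify_concordance(45272, 22000), "vbp_above_real")
  # boundary: exactly on the band edge counts as concordant
  expect_equal(classify_concordance(100, 120, band_fraction = 0.2), "concordant")
  expect_equal(classify_concordance(100, 80, band_fraction = 0.2), "concordant")
  expect_error(classify_concordance(-10, 100), class = "vbp_domain_error")
  expect_error(classify_concordance(100, 0), class = "vbp_domain_error")
})

test_that("presentation rounding is half away from zero", {
  expect_equal(round_half_up(c(2.5, 3.5, -2.5)), c(3, 4, -3))
  expect_equal(round_half_up(45272.028812), 45272)
  expect_equal(round_half_up(3579.417476), 3579)
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(123.456, 2), 123.46)
})
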