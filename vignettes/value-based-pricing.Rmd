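---
title: "Value-based pricing of medical devices: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Value-based pricing of medical devices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vbpmed)
```

## The pricing model

Value-based pricing asks: at what device price would a new intervention
be exactly cost-effective? For a new intervention A against a comparator
B, the incremental cost-effectiveness ratio is

$$\mathrm{ICER} = \frac{cost_A - cost_B}{\mathrm{QALYs}_A - \mathrm{QALYs}_B},$$

and the cost of A splits into the device price plus all other delivery
costs, $cost_A = price_A + othercosts_A$. Writing the effectiveness
difference as $gain$ and replacing the ICER by a willingness-to-pay
threshold $w$, solving for the price gives the value-based price

$$\mathrm{VBP}_A = w \cdot gain - othercosts_A + cost_B.$$

The comparator cost is deliberately kept aggregate: splitting it into its
own price and other-cost components changes nothing when only A is being
priced. The model's assumptions are those of threshold-based
cost-effectiveness generally: a single societal $w$, per-patient costs
and effects transferable from the source CEA to the local setting, and
linearity of cost in the device price.

```{r}
inp <- cea_inputs(gain = 0.138,
                  cost_B = money(6988, "EUR"),
                  othercosts_A = money(8702, "EUR"),
                  time_horizon_months = 12)
value_based_price(60000, inp)
```

## Parameters that matter

* **`wtp_primary` (EUR/QALY, default 60,000)** — the societal ceiling; the
  price it produces is the *highest acceptable price*.
* **`wtp_secondary` (EUR/QALY, default 30,000)** — a stricter threshold
  closer to market practice for widely used devices. Together the two
  thresholds give a price band per device (`price_band()`); because the
  price is affine in $w$ with slope $gain$, the band width is exactly
  $(w_1 - w_2)\cdot gain$.
* **`band_fraction` (default 0.2)** — the half-width of the relative
  concordance band. "Similar to the value-based price" is inherently
  qualitative; ±20% is the default because it cleanly separates
  near-parity pricing (ratios ≈ 0.99–1.19 in the bundled portfolio) from
  multi-fold discrepancies (ratios ≈ 0.49–4.5), and it is configurable.
* **Exchange rates** — units of foreign currency per euro, so conversion
  *to* euro is division. This matches how appraisal documents print rates
  ("€1.00 = GBP 0.833") and removes reciprocal ambiguity. Rate tables
  carry an `as_of` tag so period-appropriate rates can be supplied;
  purchasing-power-parity adjustment is out of scope (costs from
  structurally different health systems should not be transferred by any
  exchange rate).

## Conventions for awkward inputs

* **Life-year proxies.** When a CEA reports only one-year survival
  proportions, `survival_gain_one_year()` uses their difference as the
  gain, i.e. an implicit utility weight of 1 and no discounting over the
  12-month horizon. Results carry a `life_year_proxy` flag, because this
  overstates the QALY gain whenever utility < 1.
* **Negative prices.** A negative value-based price is returned as-is
  with a `negative_vbp` flag, never floored at zero: the sign is the
  finding (the device cannot be cost-effective at any positive price).
* **Non-positive gains** are priced anyway and flagged; a portfolio tool
  must not crash on a harm-dominated record.
* **Rounding.** All pricing arithmetic is unrounded; only presentation
  rounds, half away from zero, to whole euros (`round_half_up()`).
  Currency conversion keeps 6 decimal places. One bundled device
  illustrates why presentation rounding must come last: its reported
  price traces to an unrounded QALY gain (≈ 0.1382), so exact arithmetic
  on the printed 0.138 lands 0.18% away, and the reference comparison
  checks that row to 0.2% while the other four must match to the euro.
* **Batch isolation.** `run_pipeline()` captures per-device failures
  (e.g. an unresolvable currency) in that device's `warnings` field and
  continues — committee workloads are batch-like.

## The synthetic Markov generator

The published CEAs behind real device appraisals are external models the
package does not re-implement. For validation it instead ships a generic
two-arm discounted Markov cohort simulator. A `markov_spec()` holds the
states, one row-stochastic transition matrix per arm, per-state utilities
(per cycle-year) and EUR cycle costs shared by both arms, a device price
charged once at time zero in arm A, and an annual discount rate
compounded per cycle as $(1+r)^{-t\,\ell}$ with $\ell$ the cycle length
in years.

Numerical conventions, chosen for testability: rewards are counted at
cycle start (state membership before that cycle's transition) with no
half-cycle correction by default (a `half_cycle` flag averages start and
end occupancy); the device price is never discounted. Under these
conventions the two-state constant-hazard model has an exact geometric
closed form, $\mathrm{QALYs} = u\,(1 - x^n)/(1 - x)$ with
$x = (1-p)/(1+r)$, which the test suite requires the simulator to match
to $10^{-10}$. The central algebraic guarantee is parameter recovery:
feeding a simulated model's own implied ICER back into
`value_based_price()` returns the generating device price exactly,
because the pricing equation is the inversion of the ICER definition.

```{r}
spec <- markov_spec(
  states = c("alive", "dead"),
  trans_A = matrix(c(0.95, 0.05, 0, 1), 2, byrow = TRUE),
  trans_B = matrix(c(0.88, 0.12, 0, 1), 2, byrow = TRUE),
  init = c(1, 0), n_cycles = 20, utility = c(0.8, 0),
  cost_per_cycle = c(1200, 0), device_price_A = 9000,
  discount_annual = 0.03)
made <- make_cea_inputs(spec)
value_based_price(made$implied_icer, made$inputs) # recovers 9000
```

`generate_portfolio()` emulates the statistical structure of a real HTA
portfolio: a fraction of devices (default 21%, the availability rate
observed in regional appraisal practice; the eligible count is
`round(n × fraction)` half-up so 24 devices yield 5) carry CEA
parameters drawn from randomised two-state models — QALY gains
log-normal around 0.1 and comparator discounted costs log-normal around
€10,000, matching the €10³–10⁵ magnitudes of real device appraisals,
with the arm-A transition probability calibrated by root-finding to hit
each drawn gain — over 20 annual cycles at 3% discount. Real prices are
the value-based price at €60,000/QALY times $e^{\varepsilon}$,
$\varepsilon \sim N(0, \sigma^2)$ with $\sigma = 0.5$ by default (the
log-scale scatter implied by observed real/VBP ratios spanning roughly
0.5 to 4.5). One seed controls the whole portfolio.

What the generator deliberately does **not** emulate: time-dependent
transitions, more than two health states, probabilistic sensitivity
analysis, utilities below full health in the comparator arm only, or
cost structures that differ between arms other than through survival.
Passing tests on synthetic portfolios therefore demonstrate the
*algebra and plumbing* — not that any particular published CEA is
transferable to a local setting, which remains an analyst judgement.

## Bundled data and problem sizes

The package ships a five-device cardiology portfolio from a regional
Italian HTA committee (complete with reported prices for comparison), a
24-device screening portfolio in which the 19 devices lacking CEA data
are synthetic placeholders (the appraisal record prints no parameters
for them — honest provenance over invented detail), and the appraisal's
exchange rates (GBP 0.833, BRL 5.15 per euro). The test suite exercises
the algebraic identities on 1,000 random parameter draws and the
simulator properties on portfolios of 20–24 devices with 5–40 cycle
models — sizes at which every property is checked exactly and the whole
suite runs in seconds.

## Known limitations

Cost transferability across health systems is the dominant caveat:
simple exchange-rate conversion is only defensible between systems with
comparable cost structures. The life-year proxy overstates QALY gains.
The method prices a device against the evidence of one source CEA; it
does not propagate parameter uncertainty, so the output is a point
band, not an interval with coverage. And in practice the binding
constraint is data availability — in the bundled portfolio only 21% of
devices could be priced at all.
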