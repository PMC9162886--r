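# vbpmed

Value-based pricing (VBP) of high-technology medical devices from
published cost-effectiveness parameters.

Hospital and regional HTA committees routinely approve class IIb/III and
active implantable devices at prices set by the manufacturer, with no
objective yardstick. When a cost-effectiveness analysis (CEA) of the
device exists, such a yardstick is available: the price at which the
device's incremental cost-effectiveness ratio (ICER) would exactly equal
a societal willingness-to-pay (WTP) threshold. `vbpmed` implements that
calculation as a reusable pipeline for whole device portfolios, for
analysts in HTA units, hospital pharmacy services and procurement offices.

## The model

For a new intervention A against a comparator B,

```
ICER = (cost_A − cost_B) / (QALYs_A − QALYs_B)
cost_A = price_A + othercosts_A
```

Writing the effectiveness difference as `gain` and substituting the WTP
threshold `w` for the ICER, the device price that makes A exactly
cost-effective is

```
VBP_A = w · gain − othercosts_A + cost_B
```

with all monetary terms in euro. `vbpmed` evaluates this at a primary
threshold of €60,000/QALY (the highest acceptable price) and a secondary
of €30,000/QALY, giving a price band per device. When a CEA reports only
one-year survival proportions, their difference enters as a life-year
gain (flagged in the output). Costs published in other currencies are
converted through an explicit units-per-euro exchange-rate table
(`"€1.00 = GBP 0.833"` is entered as `GBP = 0.833`; conversion to euro is
division). Real market prices are then classified against the
value-based price with a ±20% relative concordance band.

A synthetic two-arm discounted Markov cohort simulator (`markov_spec()`,
`simulate_arm()`, `make_cea_inputs()`, `generate_portfolio()`) generates
realistic portfolios — cost/QALY pairs from state-transition models, ~21%
CEA availability, prices scattered around the value-based level — for
validating the pipeline without any external data.

## Worked example

The package bundles a five-device cardiology portfolio appraised by a
regional Italian HTA committee, together with its exchange rates.
`reference_report()` recomputes every price and compares it with the
value reported in the appraisal:

```r
library(vbpmed)
reference_report()
#> Recomputed value-based prices vs reported appraisal values
#>  device_id                                    name computed_vbp_eur reported_vbp_eur pass
#>         D1                         Neovasc Reducer             6566             6578 TRUE
#>         D2 Ascyrus Medical Dissection Stent (AMDS)             2880             2880 TRUE
#>         D3                              Cardioband             7800             7800 TRUE
#>         D4                       Pascal Mitral Ace            45272            45272 TRUE
#>         D5                    Cardia Ultrasept Dia             3579             3579 TRUE
#> Rows passing: 5/5
#> Concordance tally: 2 concordant / 2 real above VBP / 1 VBP above real
#> Screening: 5 of 24 devices with usable CEA data (21%)
```

Each `computed_vbp_eur` is the device price, in whole euros, at which the
device would be exactly cost-effective at €60,000/QALY. Device D1's
reported value rests on an unrounded QALY gain, so its row is checked to
0.2% rather than to the euro. Two devices are priced close to their
value-based level, two are sold markedly above it, and one (a lifetime-
horizon mitral repair system) below it. Of the 24 devices screened, only
5 (21%) carried usable cost-effectiveness data — the binding constraint
on applying VBP in practice.

The same steps are available piecewise:

```r
rates   <- read_exchange_rates(vbp_example("rates_table1.json"))
devices <- read_portfolio(vbp_example("devices_table1.csv"), rates)
run     <- run_pipeline(devices, rates)        # 60,000 / 30,000 EUR/QALY
write_results(run, "results.csv", "figure_table.csv")
```

A thin command-line front end with `compute`, `reproduce` and `simulate`
subcommands is installed at `inst/cli/vbp.R`.

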