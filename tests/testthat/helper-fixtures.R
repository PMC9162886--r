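# Shared fixtures: the bundled example files and a rate table matching
# them, plus a generator for random EUR-denominated CEA inputs used by
# the property-style tests.

fixture_rates <- function() {
  exchange_rate_table(c(EUR = 1, GBP = 0.833, BRL = 5.15), as_of = "fixture")
}

fixture_devices <- function() {
  read_portfolio(vbp_example("devices_table1.csv"), fixture_rates())
}

fixture_screening <- function() {
  read_portfolio(vbp_example("portfolio_screening_synthetic.csv"), fixture_rates())
}

random_cea_inputs <- function() {
  cea_inputs(gain = runif(1, 0.001, 2),
             cost_B = money(runif(1, 0, 5e4), "EUR"),
             othercosts_A = money(runif(1, 0, 5e4), "EUR"))
}
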