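# trachomacost

Decision-analytic costing for trachoma elimination programs: is it worth
paying for an impact survey, or cheaper to just keep treating?

Trachoma programs run annual antibiotic mass drug administration (MDA) in
evaluation units (EUs) of roughly 100,000–250,000 people, then use impact
surveys of TF prevalence (trachomatous inflammation—follicular in 1- to
9-year-olds) to decide whether MDA continues. Surveys cost real money, and
a survey that "fails" (TF ≥ 5%, so MDA continues) can look like money
wasted. This package implements the closed-form comparison showing it
usually is not: per EU and program year, surveying first (strategy *a*)
beats blanket continuation (strategy *b*) whenever

```
C_survey + P_continuation · ucMDA · N  <  ucMDA · N
```

i.e. whenever the observed continuation rate is below the break-even rate
`P* = 1 − C_survey / (ucMDA · N)`. It is written for NTD program analysts
and health economists who want to rerun that comparison with their own
survey costs, unit costs, continuation rates and EU sizes.

The package provides:

- `evaluate_strategies()` / `breakeven_rate()` — the closed-form model
  with paired propagation of the survey-cost IQR and MDA-cost 95% CI;
- `unit_cost_model()` / `ucmda_at()` — the population-elasticity law
  `ucMDA(N) = uc_ref (N/N_ref)^−0.5` for MDA unit costs;
- `build_scenario_table()` — the cost/break-even grid across EU sizes;
- `read_eu_table()` / `summarize_portfolio()` — retrospective portfolio
  accounting for a set of surveyed EUs, with the United Republic of
  Tanzania 2017–2018 programme table included as a fixture;
- `portfolio_spec()` / `generate_portfolio()` / `simulate_breakeven()` —
  a seeded synthetic-portfolio generator and Monte-Carlo validation of
  the closed-form break-even.

## Worked example

```r
library(trachomacost)

# single EU of 100,000 people, global survey-cost and unit-cost estimates
ev <- evaluate_strategies(cost_parameters(
  ucmda = interval_estimate(0.28, 0.17, 0.35, kind = "CI95"),
  eu_population = 100000
))
ev
#> Per-EU annual cost, 2017 USD (point and range):
#>   strategy (a) survey then MDA where indicated: 17,564 (12,158-21,694)
#>   strategy (b) MDA without surveying:           28,957 (17,581-36,197)
#>   break-even continuation rate, %:              71 (62-72)
```

Surveying plus selective MDA costs $17,564 per EU-year against $28,957
for unsurveyed MDA; only if more than 71% of surveys mandated
continuation would surveying stop paying for itself. The observed global
continuation rate in 2017–2018 was 32% (170/538).

The retrospective Tanzania portfolio:

```r
summarize_portfolio(read_eu_table())
#> Portfolio of 20 EUs (4,178,319 people surveyed)
#>   continuation rate: 6/20 (30%)
#>   strategy (a) survey then MDA where indicated: $307,790
#>   strategy (b) MDA without surveying:           $409,721
#>   saving from surveying first:                  $101,931 (25%)
```

At the local MDA cost of $0.0981 per person, that saving is
`people_equivalent(101930.52, 0.0981)` = 1,039,047 people treated — the
surveys paid for themselves many times over in the year they were done.

## Analysis scripts

The `analysis/` directory holds the narrative drivers, each writing its
tables under `results/`:

```sh
Rscript analysis/01_scenario_table.R      # cost grid across six EU sizes
Rscript analysis/02_case_study.R          # Tanzania 2017-2018 accounting
Rscript analysis/03_simulate_breakeven.R  # Monte-Carlo break-even check
```

The methods vignette (`vignettes/trachoma-survey-economics.Rmd`) explains
the model, the display conventions, the synthetic-data generator and the
package's limitations.

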