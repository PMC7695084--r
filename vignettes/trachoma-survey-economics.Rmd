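---
title: "The economics of trachoma impact surveys: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The economics of trachoma impact surveys: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trachomacost)
```

## The decision problem

Trachoma elimination programs deliver annual antibiotic mass drug
administration (MDA) to evaluation units (EUs), populations typically of
100,000–250,000 people. After the recommended number of rounds, an impact
survey estimates the prevalence of trachomatous inflammation—follicular
(TF) in 1- to 9-year-olds: below 5% MDA stops; 5–9.9% triggers one more
EU-wide round; 10–29.9% three rounds; 30% or more five rounds. The
proportion of surveys returning TF ≥ 5% is the *continuation rate*,
$P_{\mathrm{continuation}}$.

A program manager whose EUs have completed their planned rounds can either

- **(a)** survey every EU and continue MDA only where indicated, or
- **(b)** skip the surveys and run another round of MDA everywhere.

Within a single program year, strategy (a) is cheaper per EU when

$$C_{\mathrm{survey}} + P_{\mathrm{continuation}} \cdot uc_{\mathrm{MDA}} \cdot \bar N \;<\; uc_{\mathrm{MDA}} \cdot \bar N,$$

where $C_{\mathrm{survey}}$ is the per-EU survey cost (fieldwork per diems
included, salaries excluded), $uc_{\mathrm{MDA}}$ the per-person annual
unit cost of MDA (antibiotics and distributor salaries/per diems
excluded), and $\bar N$ the mean EU population. Rearranging gives the
break-even continuation rate implemented by `breakeven_rate()`:

$$P^\ast = 1 - \frac{C_{\mathrm{survey}}}{uc_{\mathrm{MDA}} \cdot \bar N}.$$

Surveying saves money whenever the observed continuation rate is below
$P^\ast$. Note the model is an expectation over a portfolio: costs are
financial, single-year, and deterministic given the parameters.

## Parameters and defaults

| Parameter | Default | Units | Source/rationale |
|---|---|---|---|
| survey cost | 8,298 (IQR 6,532–10,111) | 2017 USD per EU | global median over 322 impact/surveillance surveys in 11 countries |
| MDA unit cost | six tabulated values, e.g. 0.28 (95% CI 0.17–0.35) at N = 100,000 | 2015 USD per person per year | benchmark estimates for a volunteer-delivered subnational campaign |
| continuation rate | 0.32 | proportion | 170 of 538 impact surveys, 2017–2018, globally |
| inflation factor | 1.0342 | — | 2015 USD → 2017 USD |
| elasticity | −0.5 | — | unit-cost response to EU population size |

`cost_parameters()` bundles these; `evaluate_strategies()` produces the
point estimate and bounds for both strategies and the break-even rate.

Amounts carry their price basis: `money(0.28, 2015)` will not add to a
2017-USD amount until passed through `inflate()`. Evaluation inflates
2015-basis unit costs internally; 2017-basis inputs pass through
untouched.

## Bound propagation

Published point estimates come with a survey-cost IQR and an MDA-cost 95%
CI. Bounds are propagated *paired*: the low survey cost goes with the low
unit cost, high with high. The resulting triplets are scenarios, not
formal intervals — mixing an IQR with a CI has no clean probabilistic
reading, so outputs are labelled `"range"` and reproduced as conventions,
not reinterpreted. A consequence worth knowing: with asymmetric inputs
(say a degenerate unit-cost CI against a non-degenerate survey IQR) the
"low" scenario of a derived quantity can land numerically above the
"high" one; the package deliberately does not reorder them.

## The unit-cost power law

Per-person MDA delivery is cheaper in larger populations. The package
models this as
$uc_{\mathrm{MDA}}(N) = uc_{\mathrm{ref}} (N/N_{\mathrm{ref}})^{\varepsilon}$
with $\varepsilon = -0.5$ by default: a 10% larger EU has a roughly 5%
smaller unit cost. Anchored at \$0.28 per person at $N = 100{,}000$, the
law matches all six tabulated benchmark values to within \$0.01
(`validate_against_printed()`). Because $\varepsilon > -1$, the *total*
cost of a round, $uc_{\mathrm{MDA}}(N)\cdot N \propto N^{1+\varepsilon}$,
still grows with $N$ — which is why the break-even rate climbs from 58%
at $N = 50{,}000$ to 87% at $N = 500{,}000$. The scenario grid uses the
tabulated constants directly, and the power law only for populations
between them; CI endpoints are scaled with the same law but should be
treated as approximate, since the tabulated upper bound at
$N = 500{,}000$ departs visibly from pure −0.5 scaling.

## Display conventions

Internal arithmetic is always full precision; rounding happens once, at
display.

- Grid cells truncate toward zero (`display_floor()`): \$20,166.90
  displays as 20,166 and a break-even of 0.79941 as 79%. A guard of
  10^-6 absorbs binary floating-point residue in decimal products before
  truncating.
- Narrative totals round half-up (`round_half_up()`): \$409,720.59
  reports as \$409,721.
- Within the scenario grid, `build_scenario_table()` composes its
  strategy-(a) cells from the truncated whole-dollar MDA cost and then
  rounds half-up. This composite convention was chosen because it is the
  unique one that reproduces the published grid cell for cell: whole-dollar
  MDA costs are evidently what the original tabulation combined, and no
  single rounding rule applied to the full-precision values yields every
  published cell. `build_scenario_table(raw = TRUE)` bypasses display
  entirely for onward computation.

## Portfolio accounting (the case-study engine)

`read_eu_table()` ingests a delimited per-EU table (district, EU, survey
year, survey cost, population, one-round MDA cost, TF category). MDA is a
*district* campaign: a district surveyed as two EUs carries a single MDA
cost on one row, and campaigns are keyed by district × survey year (a
district surveyed in both years has two independent campaigns). A split
district resumes MDA if **any** constituent EU returns TF ≥ 5% — the
conservative public-health reading; the roll-up emits a note when that
rule actually fires on mixed outcomes.

`summarize_portfolio()` then totals: strategy (b) is the sum of one-round
MDA costs; strategy (a) is all survey costs plus MDA over continuing
campaigns; the saving is their difference; the continuation rate is
counted at EU level. On the packaged Tanzania 2017–2018 table this yields
\$409,720.59 vs \$307,790.07, a saving of \$101,930.52 — the cent-level
wobble against the published per-row figures reflects hidden decimals in
the source's printed inputs, which is also why per-row recomputations are
tested at a \$0.25 tolerance. `people_equivalent()` divides a saving by a
local per-person MDA cost (\$0.0981 for Tanzania 2017–2018, used as a
supplied constant because its exact denominator is not reconstructible
from the printed material).

## The synthetic-data generator

`generate_portfolio()` draws EU portfolios with the statistical structure
the analysis assumes, so the whole pipeline can be exercised and the
closed form validated without external data:

- **EU populations** log-uniform on 50,000–500,000 — spanning the
  plausible EU range without favouring large EUs.
- **Survey costs** lognormal, fitted to the median/IQR by
  `lognormal_params_from_median_iqr()`: location $\ln(\mathrm{median})$,
  scale the average of the two one-sided quartile fits divided by
  $z_{0.75}$. Lognormal was chosen as a positive, right-skewed family
  parameterisable from exactly the published summaries. Because the
  published IQR is slightly asymmetric on the log scale, this fit
  reproduces the median and the quartile *ratio* exactly but places each
  individual quartile about 2.1% off the published endpoint — an
  irreducible property of any two-parameter fit holding the median exact.
- **District MDA costs** from the unit-cost power law at the district
  population (on the 2017 price basis, matching the survey costs), times
  multiplicative lognormal noise with log-scale SD 0.18 — the spread
  implied by the published 95% CI at $N = 100{,}000$.
- **TF outcomes** Bernoulli at the continuation probability (default
  0.32); continuing EUs draw a category with weights (0.6, 0.3, 0.1) over
  (5–9.9%, 10–29.9%, ≥ 30%), reflecting that most continuing surveys land
  just above threshold.
- **Split districts** with probability 0.1 (2 of 18 campaigns in the
  Tanzania portfolio).

Everything is a pure function of the spec and its single seed; the
caller's RNG state is untouched. What the generator does *not* emulate:
spatial correlation, within-EU cluster sampling, prevalence dynamics over
rounds, multi-year horizons, any dependence of survey cost on population.
Passing tests therefore demonstrate internal consistency of the cost
accounting under the stated assumptions, not fidelity to any particular
country's cost structure.

`simulate_breakeven()` sweeps the continuation probability over a grid,
draws replicate portfolios at each value, and records the mean realised
cost difference (b) − (a); `empirical_breakeven()` interpolates the zero
crossing and converts the pooled Monte-Carlo standard error through the
local slope. Validation uses a single EU of 100,000 people with costs
fixed at the medians, a grid from 0.62 to 0.80 in steps of 0.02, and
10,000 replicates per grid value — enough for a crossing standard error
near 0.01, comfortably resolving the closed-form 0.7134.

## Numerical choices and degenerate inputs

- Zero or negative populations, nonpositive MDA costs, continuation rates
  outside [0, 1] and nonpositive inflation factors are rejected at the
  boundary rather than propagated.
- A survey costing more than a round of MDA yields a *negative*
  break-even rate: surveying can then never pay for itself within the
  year, and the sign carries that information.
- Equal survey and MDA costs give a break-even of exactly 0.
- The quartile fit accepts a degenerate IQR (scale 0), which the
  generator uses for deterministic-cost sweeps.

## Limitations

Financial, single-year costs only: no economic costs of participant or
distributor time, no multi-year projection of foregone MDA, no
antimicrobial-resistance or program-confidence externalities, no survey
sample-size redesign for small EUs. Those omissions are conservative with
respect to the model's central message — at plausible parameter values,
impact surveys that "fail" still save programs money.
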