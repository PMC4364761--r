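# cacCEA

Cost-effectiveness of coronary artery calcium (CAC) testing to guide statin
allocation in asymptomatic, intermediate-risk adults.

## The problem

For adults at intermediate 10-year coronary risk (Framingham 6–20%),
clinicians can (a) follow the ATP III cholesterol guidelines, (b) put
everyone on a cheap generic statin, or (c) order a one-time CAC CT scan and
treat according to the calcium score. CAC stratifies this group sharply —
most events occur in the minority with CAC ≥ 100, and people with CAC = 0
have very low risk — but the scan costs money, carries a small radiation
risk, and statins themselves have adverse effects and a "pill disutility".
`cacCEA` is for health-economics and preventive-cardiology researchers who
want a transparent, fully scriptable Markov model of this trade-off.

## The model

A cohort matching the MESA intermediate-risk subsample composition
(N = 1,619; ATP III eligibility × CAC stratum {0, 1–99, ≥100}) advances
through annual cycles over a 5- or 10-year horizon. From the healthy state,
competing risks per cycle k are resolved on a rates scale:

    p_exit = 1 − exp(−Σ λ_c),   λ_c = −log(1 − p_c),   P(cause c) ∝ λ_c

with causes: first CHD/CVD event (annual stratum risk × effective RR;
fatal with age-specific case fatality), background mortality (life table),
severe statin reaction (on-statin only), and scan-radiation cancer death.
Strategies: `atp3` (moderate statins if guideline-eligible, adherence
0.55), `treat_all` (moderate for all, 0.55), `cac_ge1` (moderate for
1 ≤ CAC < 100, intensive for CAC ≥ 100, none for CAC = 0, adherence 0.65),
`cac_ge100` (intensive for CAC ≥ 100 only). Effective relative risk is
0.65 (moderate) or 0.55 (intensive) for recommended, adherent patients and
1 otherwise. QALYs apply age-interpolated utilities with multiplicative
decrements (statin 0.99616/year; nonfatal event 0.8351 CHD / 0.8272 CVD
with a two-year linear taper); costs (2011 USD) cover the scan, statins,
events and complications, with indirect and incidentaloma components
behind flags. Costs, QALYs and outcomes are discounted at 3%. Incremental
results are expressed as ICERs, dominance, decision labels at a
willingness-to-pay threshold, and cost-effectiveness acceptability curves
from a probabilistic sensitivity analysis (beta/gamma/triangular parameter
draws, resampled cohorts, common random numbers across strategies).

See `vignettes/cac-cost-effectiveness.Rmd` for assumptions, parameter
meanings and the reasoning behind every modelling choice.

## Worked example

```r
library(cacCEA)

ps     <- build_parameter_set()                       # Table-of-parameters registry
cohort <- generate_cohort(1619, seed = 1, mode = "exact")

atp3 <- run_strategy(cohort, "atp3",    ps, horizon = 5, outcome = "CVD", seed = 1)
cac  <- run_strategy(cohort, "cac_ge1", ps, horizon = 5, outcome = "CVD", seed = 1)
atp3
#> <strategy_outcome: atp3, 1619 patients, 5y CVD, expected_value>
#>   first events /1000: 44.3 (fatal 6.1), discounted 40.6
#>   discounted QALYs /1000: 3533.5; direct cost /patient: $2433
cac
#> <strategy_outcome: cac_ge1, 1619 patients, 5y CVD, expected_value>
#>   first events /1000: 37.5 (fatal 5.1), discounted 34.4
#>   discounted QALYs /1000: 3534.0; direct cost /patient: $2322

compare_strategies(cac, atp3, valuation = "events")
#> <comparison: dCost = $-111069, dEffect = 6.25 events /1000, dominant>

find_breakeven_cac_cost(seed = 1)
#> [1] 211.1816
```

Reading: under the guideline strategy the model projects 40.6 discounted
first CVD events per 1,000 patients over five years at $2,433 per patient;
scanning everyone and treating those with any calcium averts 6.25 events
per 1,000 *and* saves about $111,000 per 1,000 patients — the CAC strategy
dominates. The scan stops being cost-saving against the guideline strategy
if it costs more than about $211.

Decision tables across scan/statin costs, horizons, thresholds and 2×
event rates come from `run_scenario_grid(default_scenario_grid())`;
probabilistic results from `run_psa()` + `ceac()`.

## Acceptance script

`scripts/acceptance.R` recomputes the model's headline quantities from
scratch against the installed package — the 5- and 10-year event
projections under the ATP III and CAC strategies, the break-even scan
cost, and the PSA acceptance probability of the CAC strategy at a $0/QALY
threshold (250 simulations × 2,000 patients) — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
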