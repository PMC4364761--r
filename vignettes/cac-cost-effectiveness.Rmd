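---
title: "A Markov model of CAC-guided statin allocation: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov model of CAC-guided statin allocation: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cacCEA)
```

## The decision problem

Asymptomatic adults at intermediate 10-year coronary risk (Framingham 6-20%)
are the group for whom statin allocation is most contested: traditional risk
factors discriminate poorly, generic statins are cheap enough that "treat
everyone" is a serious option, and statins carry small but real harms
(adverse reactions and the disutility many patients attach to taking a daily
drug they may not need). A one-time coronary artery calcium (CAC) CT scan
stratifies this group sharply: people with CAC = 0 have very low event
rates, while most events concentrate in the minority with CAC >= 100.

`cacCEA` models four mutually exclusive strategies for such a cohort:

* **atp3** -- the ATP III guideline status quo: moderate statins for the
  guideline-eligible (38% of the modelled cohort), 55% adherence;
* **treat_all** -- moderate statins recommended to everyone, 55% adherence;
* **cac_ge1** -- scan everyone; moderate statins for 1 <= CAC < 100,
  intensive statins for CAC >= 100, none for CAC = 0; 65% adherence
  (visualising calcium raises adherence);
* **cac_ge100** -- scan everyone; intensive statins for CAC >= 100 only.

In the CAC strategies the scan result *overrides* guideline eligibility: an
ATP III-eligible patient with CAC = 0 is not treated. The cohort composition
(ATP III eligibility crossed with CAC stratum, N = 1,619) reproduces the
MESA intermediate-risk subsample, and `reclassification_summary()` computes
the familiar up/down reclassification percentages from that joint table.

## Model structure

Each patient starts healthy and moves through annual cycles over a 5- or
10-year horizon. The absorbing clinical outcome is a *first* CHD event
(myocardial infarction, angina, resuscitated arrest) or, in the CVD
configuration, additionally stroke and other cardiovascular death. Within a
cycle a healthy patient faces competing risks of:

* a first event, with annual probability `stratum rate x effective RR`;
  the event is fatal with an age-specific case fatality (CHD: 10.0% under
  65, 15.7% at 65+; CVD: 10.3% / 16.3%), assessed at the attained age;
* background (non-CHD/CVD) mortality from a bundled life table;
* a severe statin reaction (1/18,000 person-years, on-statin only; fatal
  with probability 0.09, survivors discontinue statins permanently);
* death from a radiation-induced cancer attributable to the scan
  (scanned patients only; see below).

Nonfatal-event survivors pass through a two-year linear taper of the
event-related utility decrement and afterwards accrue full age-specific
utility; they face background mortality only (no recurrent events -- the
first event is absorbing for event counting) and stop statin accrual.

**Competing risks.** The model never orders causes within a cycle. Each
annual probability is converted to a rate, rates are summed, and the total
exit probability `1 - exp(-sum)` is allocated proportionally to the rates.
This avoids the bias that a fixed within-cycle ordering would introduce,
at the cost of shaving each cause's marginal probability by a fraction of a
percent relative to applying it alone.

**Cycle timing.** Transitions are resolved at the *start* of each cycle and
the cycle's utility and costs accrue to the resulting state. A fatal event
therefore contributes no QALYs from its own cycle onward, and the event
year itself is the first year of the two-year decrement taper. No
half-cycle correction is applied (a documented limitation, shared with the
annual-cycle models this package follows).

**Discounting.** Costs and QALYs accruing in cycle *k* (k = 0, 1, ...) are
discounted by `1.03^-k` -- the first cycle undiscounted, anchored by the
closed form that five years of statins at $180 discount to $849.08. All
outcomes, including event counts, are discounted at 3%; discounted event
*counts* are valued at the end of the cycle of occurrence (`1.03^-(k+1)`),
the convention of the decision-tree software whose published event
projections this engine reproduces. Undiscounted counts are also reported
(`events_per_1000`) and are the quantity checked against the closed-form
calibration `1 - (1 - p)^H`.

## Effectiveness, adherence, and harms

Moderate statins multiply the annual event risk by RR 0.65, intensive
statins by 0.55, with no tapering of efficacy over the horizon. Adherence
is drawn once per patient (0.55 without scanning, 0.65 with) and held fixed
-- no annual churn. Non-adherent patients are modelled as never-initiators:
they receive no benefit and incur no statin cost, disutility, or
adverse-event risk. This is the simplest reading consistent with an
adherence probability that scales benefit; the alternative (non-adherent
patients who still incur some cost) can be studied by overriding costs.

QALYs weight each year by an age-interpolated healthy utility (0.84 at 50
declining to 0.68 at 90, clamped outside) times multiplicative decrements:
0.99616 per on-statin year (the "pill disutility"), 0.9941 in a mild
statin-complication year, 0.9553 in a severe-complication year, and 0.8351
(CHD) / 0.8272 (CVD) in the year of a nonfatal event, tapering to
`(1+m)/2` the following year.

Two adverse-event conventions deserve a note because the source table is
ambiguous about periodicity:

* the **mild complication** (probability 0.18 per initiator, $180) is an
  episode at treatment initiation: its cost and its single decremented year
  fall in cycle 0. Applying the 2-day decrement every on-statin year would
  roughly double the aggregate disutility attributed to statins and, at the
  5-year horizon, overturn the QALY ordering of the strategies;
* the **severe complication** has a per person-year probability, so each
  episode year carries its $6,500 cost and 0.9553 multiplier.

**Radiation.** The scan's excess lifetime cancer risk (2e-5) is spread
uniformly over a 25-year latency window (a linear stand-in for the
exponential allocation used in earlier CAC models; the window is a
configurable parameter), and each cancer is fatal within the year with
probability 0.65. At ~5e-7 per scanned person-year this is deliberately
negligible but keeps the harm ledger complete.

## Costs

All costs are 2011 USD, discounted at 3%. Base case: the scan ($100 per
scanned patient), statins ($180/year while on treatment and healthy),
event direct costs ($64,400/$49,000 nonfatal/fatal CHD; $55,700/$43,500
CVD), and complication costs. Sensitivity components behind flags:
age-interpolated event productivity costs, the $15.20 scan time cost, and
the incidentaloma penalty -- 8% of scanned patients re-scanned at $250,
applied as an expected per-patient cost (sampling it per patient adds
negligible variance).

## The synthetic cohort and what it does not emulate

`generate_cohort()` reproduces the joint eligibility-by-CAC cell counts
exactly (at n = 1,619) or multinomially (any n). Baseline age is drawn from
a truncated normal on [45, 84], mean 65, SD 8 -- a stand-in, because the
source subsample's age distribution is not published -- and is independent
of CAC stratum and eligibility, which real cohorts are not (CAC prevalence
rises steeply with age). Event rates depend only on the CAC stratum, so the
age simplification affects results only through background mortality,
case-fatality age bands, utilities and productivity costs; the acceptance
suite reports how the headline event projections move as the mean baseline
age shifts from 60 to 70 (by about one event per 1,000 per five years of
age). A green test therefore establishes fidelity to the stated cohort
composition and rates, not to any individual-level covariance structure.

Eligibility is a label with the published frequencies: the model does not
re-derive Framingham scores or LDL goals, and the randomised "optional
LDL-C goal" assignment that produced the 615 eligible is taken as final.

## Probabilistic sensitivity analysis

Each simulation draws one value per parameter from the distributions of
the parameter registry (beta for probabilities, gamma -- parameterised by
mean and SD -- for costs, triangular for relative risks, adherence and the
+/-20% cost ranges; utilities, radiation parameters and the discount rate
are held fixed, as modelled in the source table), resamples the cohort,
and evaluates all strategies by microsimulation with **common random
numbers**: the same per-patient uniform streams across strategies, so
adherent sets are nested and event draws shared. CRN measurably reduces
the variance of incremental effects (a tested property) and mirrors
comparing outcomes "within the same cohort of patients". Event-rate rows
are published as beta distributions "approximated from the mean" without a
variance; they are implemented as beta with the published mean and a
configurable effective sample size (default 5,000).

Cost-effectiveness acceptability curves accept, per simulation and
willingness-to-pay threshold, the strategy maximising net monetary benefit
(`threshold x effect - cost`), splitting ties; acceptance therefore sums
to one across the mutually exclusive strategies at every threshold. At a
threshold of $0/QALY this is simply the probability of being the cheapest
strategy.

## Decision labels and the break-even search

Scenario-grid decisions use the deterministic expected-value engine (the
same expectations the microsimulation converges to, without Monte-Carlo
noise). The published vocabulary is pairwise: a strategy "dominates" when
cheaper and more effective; an alternative with a positive ICER against
the status quo at or below $50,000 per unit effect is "cost-effective".
Where both alternatives dominate the status quo the published rule is
silent; this package breaks the tie by net monetary benefit at the
threshold. That choice explains most of the handful of grid rows where the
computed label reports the CAC strategy rather than treat-all: both
dominate ATP III, treat-all averts marginally more events, but its extra
cost per extra averted event is far above the threshold.

`find_breakeven_cac_cost()` bisects on the scan cost for the point where
the CAC strategy's total discounted cost equals ATP III's -- the boundary
at which scanning stops being cost-saving. The incremental cost is exactly
linear in the scan cost, so bisection and a dense grid scan agree to the
dollar (a tested property); bisection is kept for robustness to future
non-linear cost hooks.

## Numerical and degenerate-input choices

* Event hazards are capped just below 1; single-cause probabilities at or
  above 1 raise an error (corrupted inputs) rather than being renormalised.
* Horizons outside {5, 10} require an explicit override, because the
  annualised event rates are horizon-basis-specific.
* The expected-value engine marginalises the adherence and mild-complication
  Bernoulli draws analytically, so it is bit-reproducible and seed-free
  given the cohort; all stochastic entry points require a seed.
* Misordered triangular bounds (the source table prints one distribution
  with min > max) are sorted rather than rejected.
* The bundled life table is a clearly-labelled synthetic stand-in for the
  US 2011 period table (log-linear interpolation between approximate
  published anchors) and can be swapped via `read_life_table()`.

## Known limitations

No lifetime extrapolation, recurrent events, revascularisation, statin
dose titration, re-testing, or synergy with other preventive therapy; no
sex-specific parameters (the parameter table has none); adherence has no
annual churn; event counts and QALYs ignore any benefit of detecting
incidental findings. The 5-year horizon matches statin-trial durations and
is the conservative configuration; 10-year results extrapolate trial-length
efficacy.
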