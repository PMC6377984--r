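---
title: "Methods: a decision-tree + Markov cost-utility model of bariatric surgery in type 2 diabetes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a decision-tree + Markov cost-utility model of bariatric surgery in type 2 diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baricea)
```

## The question and the model

Bariatric surgery is an effective but expensive treatment for type 2
diabetes in morbidly obese patients (BMI above 32.5 kg/m²). Whether the
up-front surgical fee is justified by downstream savings and
quality-of-life gains is a health-economic question, answered here from a
healthcare payer's perspective with the standard two-stage structure used
throughout health technology assessment:

1. **A year-1 decision tree.** Each strategy arm — `surgery` versus
   `no_surgery` (conventional medical management) — deposits its cohort
   into five mutually exclusive diabetes outcome states at the end of the
   first year: *remission*, *improved*, *persistent*, *uncontrolled* and
   *dead*. The state definitions follow ADA-derived clinical practice:
   remission is HbA1C below 6.5% off all antidiabetic agents; improved is
   HbA1C below 6.5% on metformin monotherapy; persistent is a two-class
   regimen; uncontrolled is more than two drug classes.
2. **An annual-cycle Markov cohort chain.** From year 2 onward the
   cohort's probability mass moves between states through a 5×5
   row-stochastic transition matrix, with *dead* absorbing. The trace is
   a deterministic expected-value simulation — no Monte Carlo error — run
   to a 50-year horizon.

Each cycle `t` accrues cost $\sum_s \pi_t(s)\,c(s)$, life-years
$\sum_{s \ne \text{dead}} \pi_t(s)$ and QALYs $\sum_s \pi_t(s)\,u(s)$,
each discounted by $(1+r)^{-t}$. The surgical fee is charged once at
entry (cycle 1). Comparing the two arms yields the incremental cost
$\Delta C$, incremental effects $\Delta E$, and the ratios

$$\mathrm{ICER} = \Delta C/\Delta \mathrm{LY}, \qquad
  \mathrm{ICUR} = \Delta C/\Delta \mathrm{QALY},$$

judged against a willingness-to-pay (WTP) band of 150,000–200,000
THB/QALY (one to three times Thai GDP per capita). When one arm is
cheaper and at least as effective it *dominates*; no ratio is reported
then, because a signed ratio is uninterpretable.

## Parameters, units and defaults

The bundled baseline (`default_config()`) carries, in 2017 THB:

| Parameter | Default | Notes |
|---|---|---|
| Year-1 probabilities, surgery | 0.8356 / 0.0411 / 0.0099 / 0.1233 / 0.0001 | printed vector sums to 1.0100; renormalized at load with a warning |
| Year-1 probabilities, no surgery | 0.0001 / 0.23 / 0.17 / 0.5998 / 0.0001 | sums to 1 exactly |
| Surgery fee | 150,000 (126,200–157,500) | one-time, surgery arm only |
| Metformin / sulfonylurea / TZD / AGI / insulin | 538.6 / 162 / 12,840 / 1,155.6 / 3,480 per year | drug-class annual costs with sensitivity ranges |
| Supplementation | 396 (367.2–568.8) per year | vitamin + calcium after surgery |
| Complication management | 15,326.4 (3,672–25,895) per year | accrues in the uncontrolled state |
| Utilities | 0.83 / 0.80 / 0.78 / 0.75 / 0 | per state, dead fixed at 0 |
| Discount rate | 3%/yr | applied to costs and, separately configurable, to effects |
| Horizon | 50 annual cycles | |
| WTP band | 150,000–200,000 THB/QALY | |

Per-state annual costs are *composed* from unit costs at load:
remission accrues supplementation only; improved accrues metformin
monotherapy; persistent accrues metformin plus one second agent;
uncontrolled accrues a multi-drug bundle plus complication management.
The choice of second agent (sulfonylurea — the cheapest and most common
first add-on in Thai practice) and of the uncontrolled bundle
(metformin + sulfonylurea + insulin) is **not** pinned down by the
published cost table; both are explicit assumptions, stated in the
configuration file and changeable there without touching code.

### The years-2+ transition matrix is an assumption

No annual transition matrix for this population has been published; the
long-run dynamics behind reported lifetime results rest on literature
relapse probabilities that are not printed anywhere usable. The engine
therefore accepts any row-stochastic matrix from the configuration, and
the bundled default is deliberately minimal and parametric: alive states
persist, except an annual remission→improved relapse probability
(default 0.05/yr, consistent with long-term post-bariatric relapse
accumulating to roughly 25–50% over 5–10 years in follow-up studies) and
a flat 0.0001 annual death probability from every alive state (matching
the year-1 death entries). The relapse probability is exposed to the
sensitivity analysis.

Two consequences of this default are worth stating plainly, because they
are properties of the assumption, not of the method:

* Under it, the surgery arm's annual costs stay low while the comparator
  keeps paying for uncontrolled diabetes, so over a 50-year horizon
  surgery becomes *cost-saving* (dominant) rather than merely
  cost-effective. Published lifetime totals for this comparison instead
  show surgery remaining more expensive; reproducing them would require
  the unpublished transition dynamics. The package therefore treats
  lifetime totals as model outputs to be inspected (`cea()`,
  `threshold_year()`), and validates the *arithmetic* — incrementals,
  ratios, verdicts — against printed totals fed in directly
  (`cea_from_totals()`).
* The first cost-effective horizon reported by `threshold_year()` (year
  11 at 150,000 THB/QALY under the defaults) likewise depends on the
  relapse assumption; with more pessimistic long-run dynamics the
  crossing moves earlier or later.

### Cycle accounting

Accrual is end-of-cycle: cycle `t` is discounted at exponent `t`, and
the decision-tree year (cycle 1, which also carries the surgical fee) at
exponent 1. No half-cycle correction is applied by default — an
`half_cycle = TRUE` option averages start- and end-of-cycle occupancy
for cycles 2+ for users who want it. Discount rates for costs and
effects are separately configurable but default to the same 3%.

### Numerical conventions

* Year-1 probability vectors whose sum is within ±0.015 of 1 are
  renormalized with a classed warning (`baricea_renormalized`); the band
  exists because the published surgery-arm vector itself sums to 1.0100,
  and printed inputs must load. Sums outside the band are errors.
  Renormalization preserves within-vector ratios and is idempotent.
* Transition matrix rows must sum to 1 within 1e-9 and are then exactly
  renormalized; the dead row must be (0,0,0,0,1).
* Occupancy mass is conserved to 1e-9 per cycle (tested), and the
  iterative trace agrees with matrix powers to the same tolerance.
* Classification fallback: the four clinical definitions do not cover
  every input (e.g. HbA1C ≥ 6.5% on no drugs, or a controlled patient on
  one non-metformin agent). Such records are conservatively assigned
  *persistent*, and each fallback is logged via a
  `baricea_fallback` condition so analyses can audit them.
* WTP boundary: a ratio exactly at a threshold counts as cost-effective
  (the ≤ convention).
* Reporting precision follows the field's printed conventions:
  probabilities 4 dp, percentages 1 dp, THB 2 dp.

## One-way sensitivity analysis

`one_way_dsa()` reruns the full two-arm model twice per parameter (range
ends from the configuration; published cost ranges where they exist,
±10% of baseline elsewhere, truncated to [0,1] for probabilities and
utilities — the source literature's "ninety percent interval" is not
defined precisely enough to use). Year-1 probabilities are varied by
rescaling the complement states proportionally so the vector still sums
to 1. Tornado ordering sorts by the swing `|ICUR_high − ICUR_low|`, with
a dominant end counted as ratio 0 and alphabetical tie-breaks, so output
is deterministic down to CSV bytes. A zero-width range is an exact no-op
and reproduces the baseline ICUR identically (tested).

## The synthetic cohort generator

`generate_cohort()` emulates the structure of a 73-patient retrospective
surgical cohort so the patient-level pipeline runs without any data
access: sex Bernoulli(0.589 female), age N(41.8, 12.2²) truncated at 18,
baseline BMI N(50.1, 10.3²) truncated above the 32.5 inclusion floor,
baseline HbA1C N(7.6, 1.9²) floored at 4.0, year-1 BMI N(36.9, 8.9²),
and a year-1 outcome state drawn from the surgery arm's renormalized
probability vector. Truncated draws use inverse-CDF sampling, so
generation is deterministic given the seed.

Year-1 HbA1C and the medication list are drawn *conditional on the
assigned state* (below 6.5% with no drugs for remission, metformin alone
for improved, two and three drug classes for persistent and
uncontrolled), which guarantees `classify_status()` recovers the
assignment with zero mismatches — the round-trip contract the tests
enforce. The price is that marginal year-1 HbA1C moments sit below the
unconditional target (most of the cohort is in remission and truncated
below 6.5%), and truncation shifts the baseline BMI mean up by about
1 kg/m²; the moment tests therefore check sample means against the
truncated-distribution expectations, which is what the generator
actually promises. What passing tests show is that the pipeline is
correct *on data with this idealized structure*; real cohorts have
correlated endpoints, measurement error, loss to follow-up and coding
noise that the generator deliberately does not emulate.
`exact_count_cohort()` fixes the state counts instead of sampling them,
for exact reproduction of printed proportions (61 remitters of 73 gives
0.8356 at 4 dp; no integer count over 73 can produce the printed
persistent-state probability of 0.0099, so exact-count fixtures use 0).

## Known limitations

* Lifetime results inherit the parametric transition assumption; they
  are not a validated forecast for any real population.
* Background mortality is flat (no age/sex life tables) and there are no
  tunnel states; both are out of scope for this model structure.
* The cohort generator draws endpoints independently within a record.
* CPI rebasing (`cpi_adjust()`) accepts any index table; the bundled
  `synthetic_cpi.csv` is an illustrative series for examples and tests,
  not an official statistic.

## Problem sizes used in the tests

The suite runs the full 50-cycle model, a 16-parameter sensitivity
analysis and cohorts up to n = 10,000 (for 3-standard-error recovery of
outcome probabilities and truncated clinical moments); property checks
iterate over a handful of seeded random transition matrices at horizons
of 10–25 cycles, chosen to exercise every code path at sub-second cost.
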