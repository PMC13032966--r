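---
title: "Model and methods: genotype-guided capecitabine dosing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: genotype-guided capecitabine dosing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpydcea)
```

## The decision problem

Capecitabine, an oral prodrug of 5-fluorouracil, is catabolised by
dihydropyrimidine dehydrogenase (DPD), encoded by *DPYD*. Carriers of
reduced-function *DPYD* variants (intermediate and poor metabolizers,
treated here as one "variant" group) accumulate active drug and face
substantially higher risks of severe (grade 3/4) toxicity,
toxicity-related hospitalization and treatment-related death.
Pharmacogenomic guidelines therefore recommend pre-treatment genotyping
with an upfront dose reduction to 75% for carriers.

`dpydcea` models, for a cohort of 62-year-old women starting capecitabine
monotherapy for metastatic breast cancer, whether paying for the genotyping
test (and accepting its downstream consequences) is good value for a US
healthcare payer. The two strategies differ only in the starting dose of
variant carriers: with genotyping, carriers start at the 75% dose; without
it, everyone starts at the standard dose and carriers are only
dose-reduced reactively, after their first toxicity.

## The cohort state-transition model

The model is a discrete-time Markov cohort model with a monthly cycle.
The published four-state structure (progression-free at starting dose,
progression-free at reduced dose, progressed, dead) is expanded so that
every transition probability is a pure function of the state label:

* six progression-free (PF) states — genotype (variant / wild type)
  crossed with dose tier (1.0 / 0.75 / 0.5),
* one Progressed state, and
* three absorbing, cause-tagged death states (background,
  treatment-related, post-progression disease death).

Genotype never changes; the dose tier only steps down
(1.0 → 0.75 → 0.5, floor absorbing), one step in the cycle after each
toxicity. Progression is irreversible and stops treatment; disease death
occurs only from the Progressed state.

### Within-cycle event cascade

A cycle resolves competing events in a fixed conditional order:

1. background death (monthly probability from the life table at the
   cohort's integer attained age),
2. among survivors in PF states, treatment-related death,
3. among survivors, progression (from PF) or disease death (from
   Progressed),
4. among PF non-progressors, grade 3/4 toxicity; a toxic patient is
   hospitalized with the conditional probability for their genotype/tier
   and moves to the next-lower dose tier for subsequent cycles.

Residual mass self-loops. The cascade makes within-cycle events mutually
exclusive for an individual, which keeps the cohort recursion a plain
matrix product and lets an individual-level simulation reproduce it
exactly (see "Validation"). The ordering itself is a modelling convention
— no ordering is implied by the published state diagram — and at monthly
probabilities of this size the ordering changes results by well under a
percent; what matters is that the cohort engine and the microsimulation
share it by construction.

Treatment-related death is applied in every on-treatment cycle. The
alternative reading — a risk confined to the first cycles of therapy
("early" toxicity deaths) — is available as a scenario by editing the
per-cycle probabilities, but uniform application is the default because
the monthly probabilities were published as monthly probabilities.

## Parameters

All parameters live in one validated record (`default_parameters()`),
which is the single source of truth for every analysis stage. Key values:

| group | parameter | value |
|---|---|---|
| cohort | start age | 62 years |
| | variant-carrier prevalence | 0.063 (range 0.03–0.08) |
| economics | annual discount rate | 3% |
| | willingness to pay | $100,000/QALY |
| toxicity / month | variant std / variant red / wt std | 0.08 / 0.044 / 0.026 |
| hospitalization given toxicity | variant std / variant red / wt std | 0.40 / 0.54 / 0.60 |
| treatment death / month | variant std / variant red / wt std | 0.002 / 0.0002 / 0.0001 |
| disease | progression / month | 0.11 |
| | death after progression / month | 0.051 |
| costs (2024 USD) | capecitabine, full dose / month | 115.56 |
| | genotyping test (one-time) | 174.81 |
| | hospitalization (per event, 5-day stay) | 12,907 |
| utilities | progression-free / progressed | 0.715 / 0.443 |
| disutilities | toxicity (one month) / hospitalization (one week) | 0.125 / 0.28 |

### Filling the unmeasured genotype × dose cells

The published table measures three cells per event type (variant-standard,
variant-reduced, wild-type-standard). The model needs all six PF cells.
Toxicity and treatment-death probabilities scale proportionally with the
dose fraction from the genotype's nearest measured anchor — wild type at
0.75 is `0.026 × 0.75`; the variant floor tier scales the *reduced-dose*
anchor, `0.044 × (0.5/0.75)`, preferring the measured 75% value over the
assumption-heavy extrapolation from 100%. Hospitalization given toxicity
shows no monotone dose trend in the measured cells (0.40 at standard vs
0.54 at reduced dose — a property of the source data, transcribed as
printed), so it is not dose-scaled; unmeasured cells reuse the genotype's
nearest anchor.

The hospitalization probabilities are interpreted as conditional on a
toxicity event despite being tabulated as "monthly" probabilities: read
unconditionally, 0.4–0.6 hospitalizations per patient-month would add
several thousand dollars per month and is incompatible with lifetime
totals in the low thousands; the conditional reading reproduces the
reported cost magnitude.

### Distributions for probabilistic analysis

Each uncertain parameter carries a published sampling distribution,
transcribed as printed: Beta(α, β) for probabilities and utilities;
Gamma for costs, printed as (mean, sd) and converted by moment matching
(`shape = (mean/sd)²`, `scale = sd²/mean` — shape/rate or shape/scale
readings of the printed pairs give absurd means, and the printed first
arguments equal the base-case means); Triangular printed as
(min, max, mode) for the treatment-death probabilities, whose implied
means `(min+max+mode)/3` equal the base-case values exactly. Two Beta
entries have analytic means visibly offset from their base-case values
(variant standard-dose toxicity, Beta(8.6, 94.5) → 0.083 vs 0.08;
variant standard-dose hospitalization, Beta(12, 18.9) → 0.388 vs 0.40);
they are carried as printed and the self-consistency test documents the
offset. Parameters without a printed distribution (discount rate, body
surface area, dose fractions) stay fixed in PSA.

Deterministic (one-way) ranges default to base ± 25%, except the carrier
prevalence, which uses the literature range 3–8% (about 3–5% in people of
European descent, about 8% in people of African descent).

## Rewards, discounting, numerical conventions

* Rewards are booked at cycle start and discounted by
  `(1.03)^(-t/12)` for cycle `t`; the genotyping test cost is charged at
  cycle 0, undiscounted.
* A cycle contributes `u(state)/12` QALYs and `1/12` life-years per live
  occupant; drug cost `115.56 × tier` per PF occupant; each toxicity
  event subtracts `0.125/12` QALYs (a one-month disutility — no duration
  was published, one cycle is the natural unit); each hospitalization
  subtracts `0.28 × 7/365.25` QALYs (a one-week disutility, as published)
  and costs $12,907. The two disutilities stack for hospitalized
  toxicities; avoiding the overlap changes QALYs in the fifth decimal.
* Life-years are discounted, like costs and QALYs, so that the two ICERs
  (per QALY, per life-year) are mutually consistent with one incremental
  cost.
* No half-cycle correction by default (matching the common
  decision-software default); `run_cohort(half_cycle = TRUE)` applies a
  trapezoid correction to the state-occupancy reward streams as a
  scenario.
* The cohort ages continuously from 62; background mortality is looked
  up at the integer attained age and converted to a monthly probability
  by `1 − (1 − q)^(1/12)`. The horizon is age 100, with early exit once
  live occupancy falls below `1e-8`.
* Disease-management and death costs are omitted: they were taken as
  equal across arms, so they cancel from every incremental quantity;
  totals therefore cover drug, test and hospitalization only.
* Monthly proration of the 21-day dosing regimen uses a 30-day month
  (configurable): `1,250 mg/m² × 1.8 m² × 2 × 14 days = 63,000 mg` per
  regimen cycle, $80.64 at $0.64/500 mg, $115.20/month — within 0.5% of
  the tabulated $115.56 (price-file rounding).

## Background mortality: a synthetic life table

The one external input a payer-perspective US analysis needs is female
background mortality. The package ships a *synthetic* stand-in built from
the Gompertz law `q(age) = 1 − exp(−a·e^{b(age−60)})` with `a = 0.0065`,
`b = 0.085`, chosen to approximate published US female annual death
probabilities over ages 60–100 (e.g. `q(62) ≈ 0.0077`). The fixture CSV
is regenerated by `gompertz_lifetable()` and a test asserts fixture and
code agree. Two reasons this approximation is safe here: adult all-cause
mortality is very close to log-linear in age over this range, and
background mortality is a minor competing risk next to the disease
(post-progression mortality is 0.051/month ≈ 0.6/year). Users with an
official life table can supply it via `read_lifetable()`.

## Validation: microsimulation as an independent oracle

`simulate_patients()` draws individual trajectories with the identical
event ordering, reward timing and discounting as the cohort engine, and
`validate_against_cohort()` compares mean cost, QALYs and life-years per
arm between the two computations in Monte-Carlo standard-error units.
Because the two implementations share only the parameter record — one
propagates expectations, the other samples — agreement (|z| < 3 on every
stream) is a strong end-to-end check of the transition algebra and reward
accounting. The shipped tests run 12,000–20,000 patients per arm, sizes
at which the standard errors are a fraction of a percent of the totals.

What the generator emulates — and does not. The microsimulation
reproduces exactly the world the cohort model assumes: homogeneous risks
within genotype × tier, memoryless monthly transitions, no correlation
between toxicity and progression, perfectly known genotype. Passing
oracle tests therefore demonstrates internal correctness, not external
validity: real patients have heterogeneous risks, imperfect test
coverage of *DPYD* alleles, and toxicity management more varied than a
deterministic 25-percentage-point dose step.

## Sensitivity analyses

* `one_way()` / `prevalence_sweep()` evaluate the full two-arm model on a
  grid of one parameter; `tornado()` ranks parameters by the absolute
  ICER span between their low/high endpoints (sorted by span then name,
  so output is independent of input order), reporting the top six by
  default.
* `run_psa()` performs common-draw Monte Carlo: one sampled parameter
  record per iteration, both arms evaluated on it, classification by
  incremental net monetary benefit `NMB = ΔQALY·λ − Δcost` at
  λ = $100,000/QALY, with `dominant` (cost-saving) reserved for draws
  with lower cost and more QALYs. Draws with ΔQALY = 0 are classified by
  cost sign. `ceac()` traces the acceptability curve over a λ grid. The
  default run is 10,000 iterations from one seed; all draws flow through
  R's global stream, so a seed fixes the full result bit-for-bit.

## Base-case behaviour and a known limitation

With the default parameters the package computes, per patient:
no-genotyping cost ≈ $2,562, 1.188 QALYs, 2.235 life-years; genotyping
≈ $2,687, 1.189 QALYs, 2.236 life-years; Δcost ≈ $124, ΔQALY ≈ 0.00084,
ΔLY ≈ 0.0013, ICER ≈ $148,000/QALY. The incremental effect is small
because the only mortality channel genotyping touches is the carriers'
treatment-death differential (0.002 vs 0.0002 per month) over the few
months an untested carrier spends at the standard dose before reactive
dose reduction — roughly a 1% absolute death-risk difference per carrier,
at 6.3% prevalence. Published economic evaluations of this strategy
report materially larger incremental QALY gains than this parameter set
can generate through that channel; with the probabilities and utilities
as tabulated here, the arithmetic above is what follows. Every headline
number the package reports is recomputed live by the test suite and by
`scripts/acceptance.R`, never hard-coded, so the model's own outputs are
always internally consistent (the ICER identities hold exactly) even
where they diverge from externally reported figures. The dominant drivers
in the tornado analysis are, accordingly, the carrier treatment-death
probabilities, the test cost and the carrier prevalence.

## Problem sizes in the shipped tests

The test suite runs the deterministic model at full resolution (456
maximum monthly cycles; ~350 before occupancy exhaustion), 10,000 PSA
iterations for the probabilistic summaries, 100,000 draws for
distribution-moment checks, and 12,000–20,000 microsimulated patients
per arm for the oracle comparisons — sizes chosen so Monte-Carlo error
is far below every asserted tolerance while the whole suite stays quick
on a laptop.
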