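---
title: "Modelling the direct cost of unrecognised bipolar disorder and the value of screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the direct cost of unrecognised bipolar disorder and the value of screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdscreen)
```

## The problem and the model

Bipolar disorder usually presents first as depression, and a substantial
fraction of patients newly diagnosed with major depressive disorder (MDD) in
primary care actually have unrecognised bipolar disorder (UBP). They cost a
third-party payer far more per year than either correctly diagnosed MDD or
recognised bipolar (RBP) patients, because antidepressant monotherapy is
ineffective or actively harmful in bipolar depression. `bdscreen` asks: if
every new MDD diagnosis were screened once with an imperfect test, what
happens to five-year direct costs and to the number of patients still
misdiagnosed at the end of follow-up?

The model is a deterministic cohort (expected-value) model with four
diagnostic states — MDD, RBP, UBP, and MDD mislabelled as bipolar after an
unverified positive screen (MDD-as-BD) — followed over a `horizon` of `T`
whole years. It is in the lineage of decision-tree/state-transition budget
impact models: no interactions between patients, no incident cases after
time zero, costs constant over time.

### Parameters

All parameters live in one validated `bd_params()` object. Defaults are the
model's base case; each can be overridden individually, or via a two-section
YAML file (`read_bd_params()` / `write_bd_params()`).

| field | default | unit | meaning |
|---|---|---|---|
| `plan_size` | 1,000,000 | persons | health-plan membership |
| `mde_incidence` | 0.03 | /year | one-year incidence of a major depressive episode |
| `help_seeking` | 0.50 | fraction | affected members who see a physician |
| `ubp_prevalence` | 0.16 | fraction | new MDD diagnoses that are unrecognised BD |
| `annual_correction` | 0.15 | /year | chance a misdiagnosis is corrected without screening (consistent with a ~6-year median diagnostic delay) |
| `attrition` | 0.106 | /year | all-cause plan disenrolment |
| `referral_prob` | 0.75 | fraction | screen-positives who see a psychiatrist |
| `psych_accuracy` | 1.0 | fraction | probability the psychiatrist is right |
| `horizon` | 5 | years | follow-up |
| `c_mdd`, `c_rbp`, `c_ubp` | 11,760 / 16,092 / 23,696 | USD/yr | state costs, 2021 USD |
| `c_mdd_as_bd` | = `c_ubp` | USD/yr | cost of MDD mislabelled as BD |
| `c_screen`, `c_eval` | 15 / 230 | USD | one-time screening / evaluation fees |
| `discount` | 0.03 | /year | discount rate (year 1 undiscounted) |

The cohort size `N0 = plan_size × mde_incidence × help_seeking` (15,000 at
the base case) is carried as an exact real number internally; all person and
dollar figures are rounded only at presentation (persons half-up). The cost
of an MDD patient mislabelled as bipolar is not separately estimable from
published sources, so it defaults to the UBP cost and *tracks* `c_ubp`
through updates unless overridden explicitly — an acknowledged conservative
assumption worth exploring with `bd_params_update(params, c_mdd_as_bd = ...)`.

### Event order within a year

A model year applies, in this order:

1. **Diagnosis correction** at year start: a fraction `q` of UBP moves to
   RBP, and symmetrically a fraction `q` of MDD-as-BD reverts to MDD (the
   symmetric treatment of the false-positive state is the package's choice;
   the corrected patient pays the correct-state cost from the year of
   correction).
2. **Cost accrual** at the post-correction state counts.
3. **Discounting** by `(1 + r)^-(t-1)` — year 1 is undiscounted.
4. **Attrition** at the year boundary, applied `T - 1` times over `T` years,
   uniformly across states (the disenrolment rate is all-cause, so no
   differential attrition); disenrolled patients stop accruing cost. No
   half-cycle correction is applied.

This ordering is load-bearing: it is the unique convention under which the
base case simultaneously gives `15000 × 0.894^4 = 9582` survivors,
`2400 × 0.85^5 × 0.894^4 = 680` misdiagnosed at year 5, and the discounted
per-patient ledger of $50,936.

### The screening cascade

Screening happens once, at time zero, before any dynamics. Expected
confusion counts split the cohort; every positive is provisionally labelled
bipolar. A fraction `referral_prob` of positives sees a psychiatrist who
assigns the true diagnosis with probability `psych_accuracy`; with the
default perfect accuracy, referred false positives return to MDD and
referred true positives are confirmed RBP. Unreferred true positives are
counted as RBP (the label happens to be right); unreferred false positives
become MDD-as-BD and are costed at the UBP rate — this reading of the
cascade is what reproduces the published year-5 misdiagnosis counts, and it
is also why high sensitivity at poor specificity can *cost* money: false
positives are expensive until corrected. One-time costs
(`N0 × c_screen + referrals × c_eval`) are charged undiscounted at time
zero.

## Verification strategy

Three independent routes must agree:

- the **iterative engine** (`run_no_screening()`, `run_screening()`);
- the **closed form** `closed_form_cost()`, an analytic geometric-sum
  expression for the no-screening per-patient cost, matched to 1e-9
  relative tolerance on 1,000 random valid parameter draws;
- a **seeded microsimulation** (`simulate_microcohort()`) that flips a coin
  per patient per event; the deterministic engine is its exact expectation,
  and the test suite requires agreement within 3 Monte-Carlo standard
  errors at 200,000 patients.

Per-year ledgers additionally satisfy exact conservation identities (states
sum to survivors, discounted = undiscounted × factor), and the no-screening
cost is monotone increasing in prevalence and the UBP cost and decreasing in
the correction rate.

## The synthetic score generator

Published screening instruments come with cutoff tables of sensitivities
and specificities; such tables are the model's native input
(`read_profile()`). For development and testing the package generates its
own: `simulate_scores()` draws an equal-variance binormal population
(controls N(0,1), cases N(μ,1) with `μ = √2 Φ⁻¹(AUC)`, defaults AUC 0.92
and prevalence 0.16, matching the discriminative performance reported for a
modern BD screening algorithm) and `operating_points()` tabulates the
`score ≥ cutoff → positive` rule (ties positive) over a cutoff grid, with
percentile-bootstrap 95% CIs over resampled (label, score) pairs.

Scores are reported as **calibrated posterior probabilities**,
`logit(score) = logit(prev) + μz − μ²/2`. The transform is strictly
monotone in the latent score, so ROC operating characteristics and the AUC
are untouched; what it buys is meaningful cutoffs on the default 0.01–0.99
grid and a well-posed decision-curve analysis, in which a score cutoff is
interpreted as a threshold probability. A raw binormal latent would make
"cutoff = threshold probability" false by construction and the mid-range
net-benefit dominance of the model impossible for the synthetic stand-in.

What the generator does *not* emulate: miscalibration, covariate-dependent
score distributions, unequal group variances, verification bias, or any
structure of the real instruments beyond a single AUC. Tests passing on
synthetic profiles therefore validate the *model machinery*, not any real
instrument's performance; analyses of a real test should ingest its
transcribed cutoff table.

All randomness flows through one explicit integer seed
(`simulate_scores(..., seed =)`, `simulate_microcohort(..., seed =)`); the
bootstrap derives a deterministic child seed, so a profile with CIs is
reproducible from the population seed alone.

## Analysis layers

- `sweep_cutoffs()` evaluates every operating point of a profile
  exhaustively (no interpolation — published optima are grid optima) and
  marks the cost- and accuracy-optimal cutoffs, ties breaking toward the
  lower cutoff.
- `compare_scenarios()` and `compare_tests()` report savings, additional
  correct diagnoses, and the per-patient cost redistribution across the
  three cost buckets (MDD, RBP, misdiagnosis = UBP + MDD-as-BD).
- `one_way_sensitivity()` with `default_sensitivity_plan()` reruns both
  scenarios under the thirteen canonical variants: prevalence 11%/21%,
  the screen's CI-bound operating points (0.58, 0.97) and (0.92, 0.75),
  joint 50%/150% scaling of the RBP+UBP and MDD+UBP cost pairs ("shifting
  both values for the relevant categories", with `c_mdd_as_bd` tracking
  `c_ubp`), setting `c_mdd := c_rbp`, correction 10%/20%, and referral
  50%/100%. The "RBP = MDD" variant sets the *MDD* cost equal to the RBP
  cost: that direction reproduces the published no-screening cell
  ($64,919); the reverse does not.
- `decision_curve()` computes net benefit `sens·p − (1−spec)(1−p)·pt/(1−pt)`
  for the model, treat-all and treat-none across a threshold grid, looking
  up the profile row whose cutoff is nearest each threshold.

## Numerical choices and degenerate inputs

- Validation is total: every parameter either passes its range check or
  raises an error naming the field. Any accepted parameter set yields
  finite outputs in all downstream operations.
- Counts are expectations; nothing is ever sampled in the deterministic
  path. Zero-denominator predictive values raise a distinct
  `undefined-value` error rather than returning 0.
- `attrition = 1` collapses the model to a single costed year;
  `annual_correction = 0` leaves misdiagnoses to decay only by attrition
  (`N0·p·(1−a)^(T−1)`); an inert free screen (`sens = 0`, `spec = 1`,
  `c_screen = 0`) reproduces the no-screening trajectory exactly. All three
  are tested.
- Bootstrap resamples that lose all cases or all controls are dropped from
  the CI computation rather than contributing undefined rates.

## Problem sizes

The shipped tests use populations of 400–10,000 for score simulation,
150–200 bootstrap replicates, 200 coverage replicates, 1,000 random
parameter draws for the engine/closed-form identity, and 200,000
microsimulated patients — sizes chosen so the full suite documents the
model's behaviour at comfortable Monte-Carlo resolution while running in
about a minute.

## Known limitations

- Direct costs only; no indirect/societal costs, no QALYs, no
  cost-effectiveness ratios.
- One-time screening only; no repeat screening, no incident UBP entering
  after time zero, no time-varying or treatment-responsive costs.
- The psychiatrist gold standard is a single scalar accuracy; referral and
  evaluation costs are not discounted even if evaluations happen mid-year.
- Savings at a *published* instrument's printed two-decimal operating
  points differ from figures computed from its unrounded internal tables by
  up to ~1% — the package reproduces the model, not the unpublished extra
  decimals.
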