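---
title: "Modelling the cost-utility of antihypertensive deprescribing"
author: "deprescr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost-utility of antihypertensive deprescribing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deprescr)
```

## The decision problem

Many adults aged 80 and over take two or more antihypertensive drugs.
Where systolic blood pressure is well controlled, withdrawing one drug
("deprescribing") trades a small, sustained rise in blood pressure —
and with it extra cardiovascular risk — against fewer drug-related adverse
events and lower prescription costs. `deprescr` implements a patient-level
Markov microsimulation of that trade-off from a UK NHS/PSS perspective:
two strategies (withdraw one drug vs usual care), 3-month cycles, a
20-year (effectively lifetime) horizon, costs and QALYs discounted at
3.5% a year.

This vignette records the model structure, the conventions behind every
tunable parameter, what the synthetic cohort generator does and does not
emulate, the numerical choices, and the package's known limitations.

## Model structure

Within each cycle an alive patient faces six competing causes:
non-cardiovascular death, a coronary event, a cerebrovascular event, heart
failure, a serious drug-related adverse event (hospitalised fall or acute
kidney injury), or a minor adverse event. The cause-wise per-cycle
probabilities are built independently and combined into a single
multinomial by the *product construction*: the no-event probability is the
product of the complements, and the event mass is shared in proportion to
the marginal probabilities. This keeps the total at or below 1 for any
valid inputs and is the standard way to reconcile independently sourced
risks inside one discrete-time cycle. (A sequential-draw alternative would
order the causes and condition each on the earlier ones; with per-cycle
probabilities of at most a few percent the two constructions differ well
below Monte-Carlo resolution, and the product form is symmetric in the
causes, so it is the one implemented.)

The first serious event is also the last: the patient transitions to an
absorbing post-event state (post-MI, post-stroke, ...) whose background
mortality is multiplied by a standardised mortality ratio, and subsequent
cycles expose them only to death and minor adverse events. This mirrors
the source model, which did not model recurrent events or post-event
medication changes. Minor adverse events never change state; they carry a
one-month disutility (and an optional cost, default £0) in the cycle they
occur.

Key per-cycle probability conventions, all on the constant-hazard
(exponential) scale:

* time rescaling: `p_cycle = 1 − (1 − p_annual)^(cycle/1)`; applied to
  annual and 10-year risks alike;
* the prior-CVD multiplier (1.5) and the SMRs multiply the *hazard*
  (`1 − (1 − q)^(m·t)`), not the probability, so results stay inside
  [0, 1] for any multiplier; a probability-scale option
  (`options$risk_multiplier_scale = "probability"`) exists for sensitivity
  work;
* the treatment effect enters as relative risks scaled by log-linear
  interpolation, `RR(Δ) = RR_ref^(Δ/Δ_ref)`, and reverts to exactly 1 as a
  step function once the configured effect duration elapses (no taper).

### The reference blood-pressure difference

The published relative risks are presented as the effect of *reducing
medication*, alongside the trial's observed 3.4 mmHg systolic difference.
We therefore default `reference_delta_mmhg = 3.4`: the base case applies
the RRs as printed, and scenarios that change the BP difference (for
example the lower confidence bound, 1 mmHg) rescale them as
`RR^(Δ/3.4)`. If you instead read the RRs as quoted at a meta-analysis
BP difference (say 10 mmHg), set `reference_delta_mmhg` in the config and
the base case will interpolate down from there; `load_parameters()` warns
when a config touches the treatment effect without stating the reference,
because the two readings change every effect size in the model.

### Intention-to-treat effects, per-patient costs

One third of intervention patients (1 − 0.663) do not maintain the
reduction. The risk effect is nonetheless applied arm-wide, because the
3.4 mmHg difference is the trial's intention-to-treat contrast — it
already averages over reinstatement. Maintenance status affects only the
cost stream: non-maintainers revert to the full prescription count after
cycle 0 and incur a reinstatement-visit cost in cycle 1; every
intervention patient incurs the 4-week safety-visit cost in cycle 0.

## Economics

QALYs accrue as `utility × 0.25` per cycle. Utility is the patient's
baseline EQ-5D index times the post-event state multiplier (stroke 0.629,
MI 0.778, ACS 0.77, angina 0.88, HF 0.68, serious fall 0.797), minus an
absolute 0.15 every cycle for life after acute kidney injury (the source
describes the AKI decrement as applied every 3 months for life), minus
one-month transient decrements for TIA (0.103) and minor events, averaged
into the event cycle as `decrement/12` QALYs. The score floors at zero: no
worse-than-dead states, a conservative choice where the source is silent.
A death cycle accrues nothing.

Discounting uses the midpoint variant of the half-cycle correction: cycle
`k` is discounted at `(k + 0.5) × 0.25` years. For per-cycle accruals this
is equivalent in effect to the classic half-credit-first-and-last scheme
and simpler to reason about; `half_cycle_correction = FALSE` discounts at
cycle starts. Full survival over 80 cycles at utility 1 therefore accrues
`sum(0.25 * 1.035^(-(0:79 + 0.5)/4))` = 14.45965 discounted QALYs — the
closed form the engine is tested against at 1e-6.

### Costs are placeholders

The unit-cost table this model class relies on (consultation,
prescription, acute and long-term event costs at 2017/18 prices) is not
publicly printed. The shipped `costs` block is an order-of-magnitude UK
reference-cost placeholder, every entry flagged
`provenance = "non-paper-default"`, and `load_parameters()` warns when a
config omits costs. Event counts, QALY differences and all risk-side
results are unaffected; monetary totals, ICERs and cost-dependent
thresholds are only meaningful once real unit costs are supplied.

## The synthetic cohort generator

No patient-level trial data are distributable, so `generate_cohort()`
draws synthetic patients matching the published baseline marginals of a
deprescribing trial population aged 80+ on two or more antihypertensives:

| dimension | target | distribution | dispersion source |
|---|---|---|---|
| age | mean 84.8 y | 80 + gamma offset | SD 3.5 y, not published — default |
| sex | 51.5% male | Bernoulli | — |
| prior CVD (0/1/2+) | 42.9/29.5/27.6% | categorical | — |
| baseline EQ-5D | mean 0.769 | normal truncated at 1 | SD 0.2, not published — default |
| 10-y CVD risk | "patient-specific" | beta | mean 0.35, SD 0.15, not published — default |
| frailty | — | Bernoulli(0.5) | not published — default |
| drug count | ≥2 | 2 or 3 equiprobable | not published — default |

The truncated-normal mean is calibrated by root-finding so the *sampled*
mean hits 0.769 despite the truncation at 1. Characteristics are drawn
independently: the joint structure (e.g. risk rising with age) is
unknowable from published marginals, and no correlation is imposed. That
is the main sense in which passing calibration tests do **not** certify
realism: the generator reproduces published marginal moments, not the
joint distribution, tails or missingness of real primary-care patients.
A real cohort in the same schema can be supplied via `read_cohort()`,
including per-patient risk columns that override the beta draw.

## Uncertainty analysis

`fit_distribution()` follows the standard health-economics assignments:
beta for probabilities and utilities, gamma for costs, lognormal for
relative risks and SMRs. With a published 95% CI the lognormal takes its
median at the point estimate and `sdlog = (log hi − log lo)/(2·1.96)`;
beta and gamma are moment-matched with `se = (hi − lo)/(2·1.96)`. Where no
interval is published the convention `se = 20% of the mean` applies
(overridable per parameter). Draws violating a structural invariant
(probabilities outside [0, 1], SMR below 1) are resampled up to 100 times
and then fail loudly — never silently truncated. The BP difference itself
stays fixed in PSA: its uncertainty is already expressed in the RR
confidence intervals, and resampling both would double-count the effect
uncertainty.

`run_psa()` redraws a fresh cohort per iteration by default, so the
(ΔC, ΔQ) cloud carries parameter and first-order uncertainty together, as
in patient-level PSA practice; `fresh_cohort = FALSE` pins one cohort
*and* one engine stream, so that with all-fixed specs every iteration is
identical. CEAC ties (net-monetary-benefit difference exactly zero) split
0.5/0.5, keeping the two curves summing to 1 deterministically.

`threshold_search()` bisects on the sign of the incremental net monetary
benefit `λΔQ − ΔC` rather than on the raw ICER, because the ICER is
undefined or non-monotone across dominance regions that the search path
may cross; at the crossing the ICER equals λ, and the search reports it.
Every evaluation reuses one cohort and one seed set (common random
numbers), making the searched function deterministic; default tolerance
±£250/QALY on the achieved ICER.

## Numerical and engine choices

* **Common random numbers.** Each cycle draws fixed-shape uniform vectors
  (cause, subtype) for *all* patients, alive or dead, so the two arms
  consume identical streams; with a null treatment effect and equalised
  costs the arms are bit-identical, and incremental results carry no
  between-arm sampling noise.
* **Event-cycle conventions.** Events happen at cycle midpoints; the
  post-event utility multiplier and the acute cost apply in the event
  cycle, the long-term per-cycle cost from the following cycle.
* **Age bands** are looked up at the patient's current (advancing) age;
  life-table ages beyond the terminal row clamp to it.
* **Fraction tables** that print to 99.9% (one CHD subtype row) are
  renormalised to sum exactly to 1 at load.
* **Verification oracle.** The engine is tested against an independently
  coded deterministic Markov-cohort evaluation of a reduced model
  (single patient type, flat life table), agreeing within 4 Monte-Carlo
  SEs at n = 20,000 in both arms — plus closed-form checks (annuity,
  rescaling identities) and published worked examples.
* **Problem sizes in the test-suite.** Calibration checks run at
  n = 100,000 (the scale the model population was simulated at);
  engine-vs-oracle at n = 20,000; PSA determinism and scenario checks at
  n = 400–5,000, chosen so the whole suite stays fast while every
  stochastic assertion retains 3–4 SE headroom.

## Known limitations

* No recurrent events, no medication change after an event, no terminal
  care costs — matching the source model's stated scope.
* No acute case fatality attached to events beyond the SMR mechanism; an
  acute-fatality hook exists in the design but is disabled, as SMR-only
  is the described mechanism.
* The bundled life table is a synthetic Gompertz approximation of
  England & Wales 2016–2018 non-circulatory mortality (generated by
  `data-raw/lifetable_synthetic_ew.R`), not official statistics; supply a
  real table via `lifetable=` for substantive work.
* Cost placeholders, independence of baseline characteristics, and the
  ITT treatment of reinstatement are all documented approximations above.
* Minor adverse-event subtype composition is not published; subtypes are
  drawn uniformly over the five minor types.
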