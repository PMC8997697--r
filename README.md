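# deprescr

Patient-level cost-utility microsimulation of antihypertensive
**deprescribing** — planned withdrawal of one blood-pressure-lowering drug —
versus usual care in adults aged 80 and over, from a UK NHS/PSS
perspective. It is written for health economists and clinical researchers
who want a transparent, scriptable, fully tested re-implementation of this
class of decision model: a discrete-time Markov microsimulation driven by a
trial-calibrated synthetic cohort, with probabilistic and deterministic
sensitivity analysis built in.

## The model

Each simulated patient starts at their sampled age (mean 84.8 y), sex,
prior-CVD count, 10-year cardiovascular risk and baseline EQ-5D index
(mean 0.769), and walks through 3-month cycles for up to 20 years. In each
cycle the patient faces competing risks of:

* a **cardiovascular event** — the 10-year risk *r* is converted to a
  per-cycle probability on the constant-hazard scale,
  `1 − (1 − r)^(0.25/10)`, multiplied by 1.5 (hazard scale) for patients
  with previous CVD, split 50:50 between coronary and cerebrovascular
  disease and classified into MI / ACS / stable angina or stroke / TIA by
  sex- and age-banded tables;
* **heart failure** (age-banded annual risk 2.23–5.36%);
* a **serious drug-related adverse event** (1.74%/y, split 52:48 between
  hospitalised falls and acute kidney injury) and **minor adverse events**
  (13.7%/y);
* **non-cardiovascular death** from a bundled life table, with post-event
  states carrying standardised mortality ratios (e.g. stroke 2.72,
  heart failure 2.17) applied on the hazard scale:
  `1 − (1 − qx)^(SMR · 0.25)`.

Withdrawing one drug raises systolic blood pressure by Δ = 3.4 mmHg
(trial estimate), translated into event relative risks by **log-linear
interpolation**, `RR(Δ) = RR_ref^(Δ/Δ_ref)` — raising cardiovascular risk
(HF RR 1.290, stroke/TIA 1.108, CHD 1.009) while lowering adverse-event
risk (RR 0.685). Survivors of a first serious event enter an absorbing
post-event state with a utility multiplier (stroke 0.629, HF 0.68, ...);
TIA and minor events carry one-month disutilities and AKI a lifelong
0.15 decrement. Costs (consultations, prescriptions, safety and
reinstatement visits, acute and long-term event care) and QALYs accrue per
cycle, discounted at 3.5%/y with half-cycle (midpoint) correction, and are
compared as an incremental cost-effectiveness ratio
`ICER = ΔC/ΔQ` against £20,000–30,000/QALY thresholds, with PSA
(beta/gamma/lognormal parameter uncertainty), CEACs, bisection threshold
analysis and scenario/subgroup runs.

**Costs ship as flagged placeholders.** The published unit-cost table
behind this model class is not reproduced here; `default_parameters()`
carries order-of-magnitude UK reference costs flagged
`"non-paper-default"`. Supply real unit costs via `load_parameters()`
before relying on any monetary output.

## Worked example

```r
library(deprescr)

params <- default_parameters()           # placeholder costs, flagged
config <- simulation_config(n_patients = 20000, seed = 3)
bc <- run_base_case(params, config)
bc
```

```
Deprescribing cost-utility analysis (usual care vs medication reduction)
  reduction:         cost £    3634   QALYs  3.881
  usual care:        cost £    3571   QALYs  3.963
  Incremental (usual_care - reduction): cost £-63, QALYs 0.082 -> dominant (usual_care)
  Event incidence per 100,000 (reduction - usual care):
    hf              21855    17460    +4395
    chd             12620    12970     -350
    stroke_tia      13615    12795     +820
    serious_ae       5240     7990    -2750
    minor_ae        43205    54660   -11455
```

Reading this: over a lifetime horizon, withdrawing one drug costs these
patients QALYs (0.082 per patient here) because the 3.4 mmHg BP rise
produces more heart-failure and stroke/TIA events (+4,395 and +820 per
100,000), only partly offset by fewer drug-related adverse events. Whether
the drug-cost savings compensate depends entirely on the unit costs — with
the placeholder costs above, usual care is dominant; with real
prescription costs the comparison typically becomes a trade-off judged
against the willingness-to-pay threshold. Sensitivity machinery:

```r
psa  <- run_psa(params, simulation_config(n_patients = 5000, seed = 3),
                n_iterations = 200)
ceac <- compute_ceac(psa)                      # P(cost-effective) vs WTP
th   <- threshold_search(params, "event_risks.sae_annual_risk",
                         wtp = 20000, bracket = c(0.0174, 0.30),
                         config = simulation_config(n_patients = 20000,
                                                    seed = 3))
scen <- run_scenarios(params, default_scenarios(params),
                      simulation_config(n_patients = 20000, seed = 3))
```

A thin command-line wrapper lives at `inst/cli/deprescr.R`
(`Rscript deprescr.R simulate --n 10000 --seed 7 --out results/`).

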