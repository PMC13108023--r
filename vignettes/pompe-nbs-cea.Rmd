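---
title: "Modelling the cost-effectiveness of newborn screening for infantile-onset Pompe disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost-effectiveness of newborn screening for infantile-onset Pompe disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(pompecea)
library(dplyr)
```

## The decision problem

Infantile-onset Pompe disease (IOPD) is a rare lysosomal storage disorder:
acid alpha-glucosidase deficiency causes rapidly progressive cardiomyopathy
and muscle weakness in the first year of life, and untreated infants rarely
survive infancy.  Enzyme replacement therapy (ERT) changes that prognosis
dramatically, and it works best when started before irreversible muscle
damage — which is exactly what population-wide newborn screening (NBS) of
dried-blood-spot samples can enable.  The policy question is whether the
health gained by screening an entire birth cohort to find roughly two or
three affected infants per year justifies the cost of the programme plus
the (very large) cost of treating the survivors for life.

`pompecea` frames this as a comparison of two strategies from the public
healthcare payer's perspective:

* **NBS** — every newborn is screened; affected infants are confirmed and
  start ERT immediately;
* **No NBS** — affected infants are identified clinically and start ERT
  1.5 months later on average.

A decision tree allocates the birth cohort (affected and detected, affected
and clinically identified, unaffected) and totals the screening-programme
costs; a Markov cohort model then projects each affected patient's lifetime
course through four health states — *unable to walk*, *able to walk
independently*, *ventilator-dependent*, *death* — in 6-month cycles.
Effectiveness is measured in life-years (LY) and quality-adjusted
life-years (QALY); both effects and costs are discounted at 2% per year,
and the comparison is summarised by the incremental cost-effectiveness
ratio

$$\mathrm{ICER} = \frac{C_{\mathrm{NBS}} - C_{\mathrm{NoNBS}}}
                       {E_{\mathrm{NBS}} - E_{\mathrm{NoNBS}}},$$

computed per infant on unrounded increments, per QALY and per LY.

## Model inputs

`cea_parameters()` holds every input with its base value: the 727,288-birth
cohort, IOPD prevalence of one in 297,387 observed in large-scale Japanese
pilot screening, perfect screening sensitivity with specificity 0.9989 (a
0.11% recall rate, 48.7% of recalls proceeding to confirmatory genetic
testing), itemised costs in 2025 JPY (screening test 3,000; genetic test
38,800; disease management 347,301 per patient-month excluding the drug;
home ventilation 102,800 per month; avalglucosidase alfa 196,940 per 100 mg
vial), and health-state utilities 0.55 / 0.75 / 0.23 against a 0.95
general-population anchor, age-adjusted by the ratio of population norms to
the 16–19-year reference band (ages 90+ reuse the 80–89 band).

Two inputs deserve comment because no published point value exists for
them:

* `cost_retest` — recalled newborns are re-tested on a second dried-blood
  spot, but only a single screening-test price is published.  The default
  prices the retest like the initial assay (3,000 JPY); setting it to 0
  reproduces the narrower reading.  The choice is immaterial at the
  cohort level (800 retests against 727,288 initial tests).
* `dose_mg_per_kg` / `infusion_interval_weeks` — the dosing worksheet
  behind the published per-patient drug costs is not public.  The default,
  40 mg/kg every 2 weeks, is a deliberate calibration knob: it reconciles
  the reported per-patient lifetime drug spending (≈4 billion JPY under
  screening) far better than the 20 mg/kg label dose, which undershoots it
  by roughly half.  Both presets are one override away, and every run
  manifest records the value used.

Vials are rounded up per infusion (no sharing, the payer-perspective
convention), and infusions per cycle are computed from a 365.25-day year
(≈13.04 per 6-month cycle at 2-week intervals), never hard-coded.

## From survival curves to transition matrices

The clinically identified arm's evidence base is a pair of digitized
Kaplan–Meier curves — overall survival (OS) and mechanical-ventilation-free
survival (VFS) — from a long-running Taiwanese screening cohort of treated
patients.  `pompecea` consumes any such point list as a right-continuous
step function and splices three mortality regimes:

1. **Months 0–48** (the reliable part of the digitized curves): the
   conditional interval probability $1 - S(t_{k+1})/S(t_k)$ per cycle,
   applied uniformly to all alive states — the non-ambulatory and
   ventilator-dependent states are treated as a single advanced disease
   state sharing one survival function.
2. **Months 48–138** (the curve plateau): age-matched general-population
   mortality from the life table, converted by
   $1-(1-p_{\mathrm{annual}})^{0.5}$.
3. **After month 138**: walkers revert to general-population mortality
   (scaled by `ambulatory_hazard_multiplier`, default 1 — i.e. no residual
   excess, the stated end state); non-walkers and ventilated patients add a
   constant excess hazard of 0.0257 per year — a proxy from long-term
   ventilated Duchenne muscular dystrophy cohorts — combined with
   background risk as independent risks,
   $1-(1-p_{\mathrm{bg}})(1-(1-e^{-h\cdot 0.5}))$.

The excess hazard's published figure carries no unit; this package treats
it as *per year*.  Per year implies a median of roughly 27 additional years
on ventilation, consistent with the prolonged-support proxy cohort; per
month would imply a ~2-year median, implausible for that population.  The
field is configurable with an explicit unit.

Ventilation onset is isolated by decomposition: VFS counts
ventilation-or-death as the event, so the per-cycle onset probability is
the VFS interval probability minus the OS death probability, floored at 0
(digitization noise can invert the two within a cycle).  Onset is modelled
from the unable-to-walk state only — the advanced-disease grouping implies
ventilation arises on the non-ambulatory pathway — with a switch
(`vent_onset_from_walk`) to allow onset from both alive states.

Walking acquisition enters as cumulative schedules: under screening all
patients walk by 24 months (80% by 18 months); under clinical
identification 40% ever walk, spread evenly between 12 and 30 months.  The
cumulative curve $C(t)$ is converted to per-cycle conditional
probabilities among surviving non-walkers,
$q_k = (C(t_{k+1})-C(t_k))/(1-C(t_k))$.  Walking is never lost except to
death, and the screened arm has no ventilation and background mortality
only, reflecting the observed ~150 ventilation-free months of follow-up in
screen-detected treated patients.

Within a cycle, events are ordered death → ventilation → walking and
applied as nested conditionals, so every matrix row sums to 1 exactly.
One numerical subtlety: the KM decomposition yields *unconditional* cycle
probabilities of ventilation onset, so inside the matrix the onset entry is
rescaled by $1/(1-p_{\mathrm{death}})$; the product then reproduces the
KM-derived marginal exactly rather than compounding the two.

Other numerical conventions: digitized curves that fail monotonicity are
repaired by running-minimum projection (`repair_km_curve()`, which reports
the largest correction); life-table and norm lookups use the attained
integer age `floor(cycle * 0.5)` from birth; the lifetime horizon closes at
age 110 (220 cycles), where the life table forces death and any residual
mass accrues nothing further; restricted horizons simply truncate —
survivors at the boundary are not forced to death, they are merely
uncounted.  Rewards are credited to cycle-*start* occupancy with no
half-cycle correction by default (the common default of the commercial
software used for such models); `half_cycle = "half-cycle"` switches to
mid-cycle averaging.

## Economic accrual

Each cycle contributes occupancy × cycle length × discount factor
$(1.02)^{-t}$ to LY, weighted further by the age-adjusted state utility for
QALYs.  Management and drug costs accrue in all alive states (every
surviving patient is on ERT, including while ventilated), ventilation cost
only in the ventilator state.  The comparator's 1.5-month treatment delay
is charged as a drug-cost offset on the first cycle (fraction 4.5/6); its
clinical consequences are already embedded in the arm-specific survival
and walking inputs, so no extra states are needed.  Unaffected newborns
accrue the age-adjusted 0.95 population utility under life-table mortality
and zero modelled medical cost.  Per-infant values are the
prevalence-weighted mixture of patient and general-population outcomes plus
cascade costs spread over the cohort — which is why incremental QALYs per
infant are of order $10^{-5}$ even though each detected patient gains many
QALYs.

## Sensitivity and scenario analysis

`one_way_dsa()` varies one parameter at a time over `default_ranges()` —
published plausible ranges where they exist, ±20% otherwise; prevalence is
varied upward only, to one in 100,000, since no lower bound is published —
rerunning the entire pipeline at each bound and ordering parameters by
ICER span (the tornado ordering, invariant to input order).  Runs where
one strategy dominates are recorded with their flag rather than dropped.
`scenario_horizon()` repeats the analysis over a restricted horizon
(20 years being the conventional scenario).

## The synthetic input bundle

Four external inputs are tables this package cannot redistribute: the
national life table, the digitized KM coordinate lists, age-specific QOL
population norms, and standard weight-for-age.  `synthetic_bundle()`
generates deterministic, shape-faithful stand-ins so the full pipeline
runs, tests and demonstrates end-to-end with no downloads:

* **life table** — Gompertz–Makeham hazard with an infant-mortality excess
  at age 0, closing at age 110.  The defaults were calibrated once so the
  engine's discounted general-population life expectancy at 2% is ≈40
  years (81.2 undiscounted), the regime a low-mortality population
  implies.
* **KM curves** — exponential early decline reaching a plateau by month
  48, flat through month 150, with the VFS plateau below the OS plateau.
  The plateau levels (0.70 / 0.45 by default) are free shape parameters,
  *not* published values.
* **QOL norms** — 0.95 in the 16–19 band, declining 0.02 per decade band.
* **weight-for-age** — concave power growth from 3 kg to 60 kg by age 18.

An optional seeded noise flag jitters the curves (then repairs them),
exercising the digitization-noise path.  Users with the real tables drop
their CSVs into the same five-file layout and `read_bundle()` consumes
them unchanged.

What passing tests on synthetic inputs do and do not show: they verify the
machinery — conservation, oracle agreement, splicing rules, accrual
identities, directional responses — and they land the headline outputs in
the published regime (a nine-figure ICER per QALY, drug costs ≈80% / ≈96%
of strategy totals, ≈29 QALYs per screened patient).  They do not
reproduce the published six-decimal results, because those depend on the
exact digitized coordinates, life table, norms and dosing worksheet.  With
those supplied, agreement should be limited only by digitization
tolerance.  One related caveat: reported zero-screening-cost ICERs in the
source literature are internally inconsistent (132 vs >155 million
JPY/QALY); this package simply reports its own computed value for that
scenario.

## Problem sizes and runtime

The lifetime analysis is 220 half-year cycles over 4 states per arm — a
deterministic matrix recursion that runs in milliseconds, so the full
tornado (13 parameters × 2 bounds, each a complete pipeline rerun) takes
under a second.  The microsimulation cross-check uses 100,000 individuals
against binomial standard errors; the package's validation suite runs it
at that size as a matter of course.

## Known limitations

* Late-onset Pompe disease detected incidentally by screening is out of
  scope, as are societal-perspective costs and probabilistic sensitivity
  analysis (no joint distributions are available to parameterise one).
* Management costs do not vary with walking ability (no data), likely
  understating comparator costs — though drug cost dominance limits the
  impact.
* False positives incur confirmatory-testing costs only; no downstream
  follow-up, anxiety disutility or screening-related harms are modelled.
* Utilities come from adult late-onset trial populations; no
  paediatric-specific utilities exist.

```{r example}
res <- run_cea(cea_parameters(), synthetic_bundle())
tidy(res)
glance(res)
```
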