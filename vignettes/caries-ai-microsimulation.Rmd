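---
title: "A tooth-level microsimulation of AI-assisted proximal caries detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A tooth-level microsimulation of AI-assisted proximal caries detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(cariesim)
```

## The question

Proximal caries lesions - lesions on the surfaces where neighbouring teeth
touch - cannot be inspected directly. They are found on bitewing
radiographs, and reading bitewings is error-prone: dentists' sensitivity for
early (noncavitated) lesions is low, while convolutional-network assistance
roughly doubles it at a moderate cost in specificity. Whether that accuracy
difference is worth paying for depends entirely on what happens *after*
detection: an early lesion found in time can be arrested micro-invasively by
resin infiltration, while a lesion found late (or treated restoratively)
enters the well-known restorative spiral - composite, repair, crown, root
canal treatment, retreatment, extraction, implant - in which each
intervention is more expensive than the last and buys limited time.

`cariesim` simulates this chain of consequences at the level of a single
posterior tooth followed in annual cycles from age 12 over a 65-year
horizon, under two detection strategies that differ *only* in the
radiographic accuracy profile and a per-use software fee:

* **control** - biannual-routine visual-tactile assessment (modelled as one
  assessment per annual cycle) plus bitewing radiographs every 2 years read
  by dentists alone;
* **ai** - the same schedule with the radiographs additionally analysed by a
  detection-support system.

Effectiveness is the number of years the natural tooth is retained
(undiscounted); costs are euro (2020, German mixed-payer fee logic),
discounted at 3% per year by default.

## Disease model

One proximal surface per tooth carries at most one lesion, graded
`E2 < D1 < D2 < D3` (inner enamel, then outer/middle/inner dentin; `E2`/`D1`
are "initial", `D2`/`D3` "advanced"; radiographic E1 is folded into E2
because no separate E1 inputs exist). At age 12 a surface is sound or
carries a prevalent lesion (low risk: 14% E2, 2.5% D1, 0.5% D2; the
high-risk profile multiplies these by 2.14/1.66/1.66).

Sound surfaces develop new lesions - arriving directly at E2, D1 or D2 as
competing risks - with exponentially age-decaying hazards
`m * a * 2.7^(b * 2*age)`; untreated lesions progress one stage per cycle at
most, with power-law hazards `m * c * (2*age)^(-k)` scaled by a population
risk multiplier (2.13 low, 2.63 high; the D2-to-D3 step instead uses a fixed
multiplier of 1.32). Infiltrated lesions progress with separate, much lower
hazards and no risk multiplier. The base 2.7, the doubling of age, and all
coefficients are data, not code: they live in `extdata/table1_base.json`
and are validated on load (`load_parameters()`), with hazards clamped into
[0, 1] before use as per-cycle probabilities. Both hazard families decay
with attained age, concentrating incidence and progression in adolescence,
which is what makes *early* detection the decisive lever.

```{r hazards}
development_probability(c(12, 16, 20), "E2")
progression_probability(c(12, 16, 20), "D1", risk = "low")
progression_probability(c(12, 16, 20), "E2", infiltrated = TRUE)
```

## Detection and treatment

Each due method fires independently given the truth: stage-specific
sensitivity on a diseased surface (`D3` is graded with the advanced-lesion
column; visual-tactile assessment is blind to initial stages), and
`1 - specificity` at the initial-lesion grade on a sound surface. A false
positive is always graded "initial" and - under the base policy - receives
one resin infiltration: money spent, nothing gained. Detected initial
lesions are infiltrated (base policy) or restored (`policy = "restore"`,
the harmful variant); detected advanced lesions are always restored, with a
0.3 pulp-exposure risk for D3 (then 95% direct capping / 5% immediate root
canal treatment).

One deliberately exposed design choice is what a *repeated* examination of
the same untreated lesion means (`redetect` in `build_scenario()`):

* `"per_stage"` (default): each method grades a lesion once per
  radiographic stage; a miss persists until the lesion progresses and
  presents a new appearance. Reader error on an unchanged lesion is treated
  as systematic rather than independent noise. Under this reading, low
  early-lesion sensitivity means early lesions genuinely stay undetected
  for years, which is the mechanism that separates the two strategies.
* `"per_exam"`: every scheduled exam is an independent Bernoulli redraw.
  Over 20+ biennial radiographs even a 24%-sensitive reader detects
  essentially every persistent lesion (cumulative probability above 99%),
  so the strategies converge and only detection *timing* differs.

False-positive readings of sound surfaces redraw per exam in both modes
(each new radiograph is a new opportunity to over-read a sound surface),
but by default a surface infiltrated after a false positive is book-kept
and not treated again (`refp_repeat = FALSE`).

## The failure cascade

Restored teeth follow the annual-probability transition rows: composite
restorations fail at 0.016/cycle and are re-restored, repaired, crowned,
root-canal treated or extracted (0.45/0.10/0.10/0.25/0.10); a repaired or
re-restored composite is crowned at its next failure; re-restoration
carries a 10% pulp-exposure risk. Direct capping carries an 0.111/cycle
complication rate (95% to root canal treatment). Crowns on vital teeth fail
at 0.036/cycle, root-filled crowned teeth at 0.029/cycle prosthetically
plus 0.021/cycle endodontically; failed crowns are replaced at most once.
Root canal treatment is salvaged by nonsurgical (0.085/cycle onward) and
then surgical retreatment (0.061/cycle, extraction on failure). Extracted
teeth are replaced with probability 0.8 by an implant-supported crown
(0.010/cycle complication rate, re-implanted at most once); implants accrue
costs and exams but no retention years. Within a cycle the order is disease
dynamics, then exams and treatment, then failure of previously placed work
(work placed this cycle cannot fail this cycle).

The engine is validated against a closed-form absorption computation of
exactly this chain (see `test-engine.R`): with every tooth restored at
cycle 0, the simulated extraction-time distribution matches the
transition-matrix solution within Monte-Carlo error at every checkpoint.

## Uncertainty and pairing

With `psa = TRUE` (default) every tooth draws its own realization of all
distributed inputs: accuracy values from triangular distributions spanning
their 95% confidence bounds, hazard spreads from the stated uniform or
triangular ranges, point values elsewhere. This mixes parameter and
first-order uncertainty at tooth level. `run_psa()` provides the classic
two-loop alternative (outer parameter draws, inner cohorts summarised by
their means), which is the level at which incremental clouds and
acceptability curves are usually drawn; `compare_strategies(level =
"sample")` uses it.

Randomness is strictly compartmentalised: each tooth receives a child seed
derived from the run seed, and path randomness is pre-drawn as per-purpose,
per-cycle streams (disease, each reader, failure, allocation, replacement).
Two strategies run from the same seed therefore share lesion trajectories
and reader draws and diverge only where a detection or treatment difference
intervenes - synchronized common random numbers, which stabilises
incremental statistics considerably. Distribution sampling consumes exactly
one uniform per parameter regardless of kind, keeping the streams aligned
across arms.

## Costs

Every clinical event is priced by a JSON fee schedule keyed by event kind.
Mouth-level fees (assessment, bitewing pair, AI analysis at 8 euro per pair
in the base case) are divided across the 16 posterior teeth covered by a
bitewing pair. The shipped schedule `extdata/costs_placeholder.json` is a
**synthetic placeholder** (flagged `synthetic: true`): fees drawn once,
reproducibly, from realistic German 2020 magnitudes with the ordering
infiltration < restoration < crown < implant-supported crown. It makes the
pipeline fully runnable and testable, but absolute euro results under it
are illustrative; users with catalogue-derived amounts enter them into
`extdata/costs_appendix_template.json`. Retention results never depend on
the fee schedule (asserted in the test suite).

Cost discounting multiplies a cycle-`t` cost by `(1+r)^(-t)` (start-of-cycle
convention, no half-cycle correction). Effectiveness is reported
undiscounted: a 65-year retention ceiling discounted at 3% would compress
to at most 28.6 present-value years, a scale on which none of the usual
retention summaries are read; a discounted-effectiveness column is still
recorded per tooth.

## What a run produces

```{r run}
ce <- compare_strategies("base_case", n = 500, seed = 1)
ce
```

`sensitivity_table()` sweeps the ten preset analyses (base case, high risk,
restore-everything policy, alternative dentist accuracies, AI fee 4/12
euro, 0%/100% replacement, 1%/5% discounting); `write_ce_outputs()` writes
`summary.json`, `ce_plane.csv` and `ceac.csv`.

## Numerical and design choices

* Horizon 65 annual cycles (ages 12-77), matching a full-retention ceiling
  of 65 years; configurable.
* Hazard evaluation uses the literal printed base 2.7 (not *e*) and the
  literal doubling of attained age; both are config fields
  (`age$exp_base`, `age$factor`) rather than assumptions baked into code.
* Development and progression draws use one uniform per cycle; competing
  development risks are resolved by a single categorical draw in stage
  order E2, D1, D2.
* Allocation maps must sum to 1 exactly; violating configurations refuse
  to load. Cost-effectiveness plane ties are resolved by a fixed rule
  (zero cost increment counts as "less costly", zero effect increment as
  "less effective"); acceptability ties split evenly.
* Problem sizes used by the test suite and acceptance script - 1,000-tooth
  cohorts for headline quantities, 3,000-4,000 teeth for oracle and
  monotonicity checks, 100 x 50 for the two-loop analysis - were chosen as
  the sizes at which Monte-Carlo error is comfortably below the tolerances
  being asserted.

## Limitations

The simulated conditions reproduce the *direction* of the strategy
comparison - the AI arm retains teeth slightly longer, and the high-risk
and restore-everything variants move the way one expects - but the absolute
separation between strategies is modest (about +0.2 retention years in the
base case). The printed annual failure probabilities bound how much harm a
missed early lesion can do: with composite restorations failing at
0.016/cycle, a tooth restored in adolescence loses on average only about
5-7 years by the horizon, and overall extraction rates stay in the single
digits. Larger published effect sizes for this comparison imply
substantially higher downstream failure burdens than these transition rows
generate; mechanisms such as secondary caries around restorations,
patient-level risk correlation, or bulk prosthetic failure are known
candidates and are deliberately out of scope here. The same holds for cost
dominance: under the synthetic placeholder fees the AI arm's false-positive
infiltration load (14% per radiograph at specificity 0.86) is not offset
by averted cascade costs, so the AI arm runs slightly more expensive.
Conclusions about absolute euro amounts or cost dominance require the
catalogue-derived fee schedule and should be read jointly with the cascade
caveat above.

Other simplifications: no mouth-level correlation across 28 teeth, no
misgrading of lesion depth, no reader-to-reader correlation beyond the
sampled accuracy distributions, no dropout or mortality within the
horizon, and no societal-perspective costs.
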