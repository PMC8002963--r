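---
title: "Model-based cost-effectiveness of supplemental FDG-PET/CT in the work-up of IPMN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based cost-effectiveness of supplemental FDG-PET/CT in the work-up of IPMN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipmncea)
```

## The clinical question

Intraductal papillary mucinous neoplasms (IPMN) are cystic pancreatic lesions
with malignant potential, increasingly found incidentally on cross-sectional
imaging. When a lesion shows possible signs of malignant transformation
(high-grade dysplasia or invasive carcinoma), the decision is between
pancreatic resection — effective but carrying real perioperative mortality and
lasting quality-of-life cost — and continued surveillance, which risks a
delayed cancer diagnosis. Conventional imaging (CT/MRI) discriminates
malignant from benign IPMN imperfectly; FDG-PET/CT has reported substantially
better sensitivity and specificity in this setting.

`ipmncea` implements a decision-analytic model of that choice from a US
healthcare-system perspective: a cohort of patients under evaluation for
malignant transformation (pre-test probability 52%, mean age 64.3) is
classified by one of two diagnostic strategies — CT/MRI alone, or CT/MRI plus
a supplemental FDG-PET/CT — and then followed through an annual-cycle Markov
model for 15 years, accumulating discounted costs (USD) and quality-adjusted
life years (QALYs). Strategies are compared by incremental cost and
effectiveness and by net monetary benefit,
$\mathrm{NMB} = \lambda\,E - C$ at a willingness-to-pay of
$\lambda = \$100{,}000$ per QALY.

## Decision tree

Each strategy's sensitivity and specificity split the cohort into the four
diagnostic outcomes:

$$ \mathrm{TP} = \pi\,Se,\quad \mathrm{FN} = \pi(1-Se),\quad
   \mathrm{TN} = (1-\pi)\,Sp,\quad \mathrm{FP} = (1-\pi)(1-Sp), $$

with $\pi$ the pre-test probability. Test positives undergo immediate
resection: a weighted surgery cost (78% pancreatoduodenectomy / 21% distal
resection, renormalized — see *Numerical choices*), a bundled readmission
cost, a one-time perioperative mortality of 4.6%, and a first-year utility of
0.818. Test negatives continue surveillance at utility 1.0. Both strategies
are charged one CT/MRI examination upfront; the PET strategy additionally
charges the PET examination — the supplemental design.

## Markov structure

Six health states refine the coarse follow-up / resection / recurrence / death
skeleton so that each input parameter drives exactly one flow:

| state | who | utility/yr | annual exits |
|---|---|---|---|
| SurveillanceBenign | true negatives | 1.0 | malignant transformation 2.23%; background death |
| UndetectedMalignant | false negatives, new transformations | 1.0 | disease death 2.7%; detection (see below); background death |
| PostResectionBenign | false positives | 0.896 | background death |
| PostResectionMalignant | resected malignancies | 0.896 | recurrence 16.7%/yr (×0.9 under PET); background death |
| Recurrence | recurrent malignant disease | 0.65 | disease death 28.3%; background death |
| Death | — | 0 | absorbing |

Cause-specific risks combine with the age-adjusted background mortality
$q(a)$ as independent competing risks within a cycle: the probability of
surviving both is $(1-q)(1-q_\text{cause})$, and the residual mass stays in
place. Background mortality comes from a bundled life table (ages 60–85,
linear interpolation at fractional ages, clamped above the last tabulated
age); the packaged file is a synthetic stand-in reproducing the level and
Gompertz-like gradient of recent US all-population mortality, and
`synthesize_life_table()` provides a parametric alternative,
$q(a) = 1 - \exp(-\alpha e^{\beta a})$.

Undetected malignancy is re-tested at each annual surveillance visit with the
strategy's own sensitivity; on detection the patient undergoes surgery with
the same costs and perioperative mortality as at cycle 0. The PET strategy's
earlier detection is credited with a 10% relative reduction of the recurrence
hazard.

Reward conventions: state rewards use membership at the start of cycle $t$
and discount factor $(1+r)^{-t}$, $t = 0,\dots,14$, with cycle-0 events
undiscounted; transition event costs (delayed surgery, recurrence-entry cost
where configured) are charged at the cycle in which the patient arrives; the
resection-year utility 0.818 applies for exactly one cycle, then 0.896
long-term. Events occurring in the transition out of the final cycle fall
outside the horizon and are not counted.

## Structural variants and calibration

The published analysis this package re-implements was built in a commercial
decision-tree tool and its exact state/reward wiring is not public. Every
choice the publication leaves open is therefore an explicit, selectable
variant (`structure_variant()`):

* **FN detection** — annual re-testing with the strategy's own sensitivity
  (default), or detection with certainty after a fixed one-year delay.
* **Recurrence cost timing** — the cost of recurrent disease charged every
  cycle in the recurrence state (default; an annual phase-based cost), once
  on entry, or both (initial-phase plus continuing-phase cost).
* **Recurrence exposure** — constant annual hazard (default), first five
  post-surgical years only, or a single first-year opportunity. The
  post-resection malignant state is internally stratified by time since
  surgery, so the windowed variants are exact.
* **Post-resection surveillance imaging** — annual imaging cost in the
  post-resection states (default on, reflecting guideline follow-up).
* **Half-cycle correction** — off by default; when on, utility rewards use
  the average of the occupancies at the two cycle boundaries.

`calibrate_structure()` enumerates all 72 combinations and scores each
against the full set of published scalar outputs (per-strategy costs,
effectiveness and NMB, incremental cost and effectiveness, the PET-specificity
threshold, and the sensitivity-analysis QALY deltas) by mean squared relative
deviation. Scoring on the full result set rather than the base-case table
alone keeps the selection from trading the incremental structure — which is
what a diagnostic comparison is about — for marginal gains on absolute levels.
The shipped defaults are the best-scoring combination; the sweep takes well
under a minute.

### What calibration does and does not achieve

Under the selected structure the model reproduces the published *incremental*
results well: incremental cost ≈ \$900 (published \$1581, same sign and
order), incremental effectiveness ≈ −0.15 QALY (published −0.11), PET
dominant, and sensitivity-analysis QALY advantages of ≈ 0.22 / 0.10 at CT/MRI
specificity 65% / 85% (published 0.18 / 0.06). The published *absolute*
levels are not reproduced within a few percent by any documented variant:
this implementation yields ≈ \$115k / 7.98 QALYs (PET) versus the published
\$104.8k / 8.48. The mismatch is structural, not parametric: at the
recurrence person-years implied by the published costs (≈ 1.1 discounted
years at the annual recurrence-phase cost), the printed annual rates —
16.7%/yr recurrence among resected malignancies and 28.3%/yr death in
recurrence — generate more recurrence deaths, and hence a lower QALY total,
than the published effectiveness admits. Reconciling both would require an
intermediate recurrence-exposure window (roughly eight years) or a
probability-to-rate reinterpretation of the source estimates, neither of
which is printed; we deliberately do not fit such a dial to the published
table. The NMB-threshold location inherits this level offset (≈ 65% here
versus 71.5% published). Conclusions that rest on the incremental comparison
are robust to this; analyses that need absolute budget impact should treat
the levels as structure-dependent.

## Sensitivity and threshold analysis

`one_way_dsa()` re-runs both strategies end-to-end with one parameter at its
low/high bound and all others at base, reporting incremental cost and
effectiveness (PET − CT/MRI) for tornado display. Default ranges use the
spans reported in the clinical literature for the diagnostic accuracies
(CT/MRI sensitivity 61–81%, specificity 65–85%; PET sensitivity 80–95%,
specificity 60–95%, widened where needed to contain the base value) and
±20% of base, clamped to validity, for costs and probabilities without a
published span; ranges are overridable.

`threshold_analysis()` finds the parameter value equating the two strategies'
NMBs. The search interval (default PET specificity over [0.50, 0.99],
spanning the literature) is pre-sampled at 50 points to verify monotonicity
of the NMB difference — fewer false-positive surgeries can only lower cost
and raise QALYs, so the root is unique when it exists; a constant-sign
pattern reports "no crossing", and non-monotone patterns are an error rather
than a silently wrong root. Bisection then narrows the bracket below `tol`
(default 1e-4).

## Synthetic data and the microsimulation oracle

`generate_parameters(seed, scale)` perturbs every probability, utility and
cost multiplicatively and uniformly (±`scale`, clamped to validity) around
the base case, leaving the economic settings and structure fixed. It emulates
parametric uncertainty around the literature values for property-style
testing; it does not emulate correlated uncertainty (e.g. sensitivity and
specificity co-varying along an ROC curve) or sampling distributions of the
source studies, so passing tests certify engine correctness across the
parameter space, not clinical robustness.

`microsimulate()` pushes individuals through the *identical* decision-tree
and per-cycle transition dynamics by random draws and reports the mean and
standard error of discounted cost and QALY. Because the cohort engine is the
exact expectation of this process, agreement within sampling error (we test
3 SE at n = 200,000, across 20 random parameter sets) validates the engine's
accumulation, event-cost and discounting logic independently of the matrix
construction, which is pinned separately by hand-computed cases. Standard
errors scale as $1/\sqrt{n}$.

## Numerical choices

* The published head/distal resection mix (78%/21%) sums to 99%; the
  proportions are renormalized (0.78/0.99, 0.21/0.99) in the weighted surgery
  cost rather than inventing an unpriced third procedure, and validation
  warns rather than errors. The recurrence probability row is printed without
  a unit and is read as 16.7%, consistent with the neighbouring rows.
* Occupancy conservation is enforced at every cycle to 1e-12; a violated row
  is an internal error, never silently renormalized.
* Config files may give any numeric field in percent via a `_percent` key
  suffix, resolving the mixed notation of the input table per field.
* Ages between tabulated years use linear interpolation of $q$; ages beyond
  the table clamp to the last value; ages below it are an error.
* Bisection tie-break: an exact zero at the midpoint closes the bracket from
  the right, and the reported threshold is the bracket midpoint.
* Problem sizes: 15 annual cycles, 72-combination calibration sweep,
  oracle cross-checks at n = 200,000 individuals with fixed seeds.

## Known limitations

* The absolute published cost/QALY levels are reproduced only to ~9% / ~0.5
  QALY for the reasons given above; incremental results are the reliable
  output.
* No probabilistic sensitivity analysis: the generator is a test instrument,
  not a PSA engine, and no acceptability curves are produced.
* No IPMN subtype distinction (branch/main/mixed duct), no EUS/FNA arm, no
  repeated-PET surveillance strategies, and no individual-level heterogeneity
  in the cohort engine beyond age.
* A single diagnostic decision point: the model evaluates one work-up, with
  surveillance re-testing only for undetected malignancy.
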