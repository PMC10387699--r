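---
title: "A treatment-sequence microsimulation for relapsing MS: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A treatment-sequence microsimulation for relapsing MS: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmtseq)
```

## The model

`dmtseq` simulates individual people with relapsing multiple sclerosis
through lifetime sequences of disease-modifying treatments (DMTs). The
disease state is the Expanded Disability Status Scale (EDSS) on integer
points 0–9, with death as a separate absorbing flag rather than a matrix
row — this keeps the annual transition matrix purely disease-state and
lets mortality scale with a background life table. The cycle length is
one year: annual transition matrices are the norm for EDSS models, and
treatment-effect ratios measured on 24-week confirmed disability
progression (CDP) are mapped onto the annual cycle through rate scaling
(below).

Each simulated year draws, in a fixed order chosen for reproducibility
(sensitivity to this order is a documented caveat):

1. **Death** — probability `1 − exp(−h(age) · m(EDSS))`, where `h` is the
   life-table hazard and `m ≥ 1` an EDSS mortality multiplier. A death
   suppresses everything downstream in that cycle, including accrual.
2. **Relapses** — a Poisson count with rate `ARR(EDSS) × IRR(drug)`,
   where IRR is the incidence rate ratio versus placebo.
3. **EDSS transition** — the natural-history row's total worsening mass
   `p` is scaled to `p' = 1 − (1 − p)^RR` (probability → rate → scaled
   rate → probability); conditional on worsening, the allocation among
   higher states follows the natural-history row renormalized. Trials
   measure "progression", not per-state jumps, so the relative risk acts
   only on the aggregate worsening mass; improvement transitions are
   untouched by treatment.
4. **Adverse events** — one aggregate annual discontinuation probability
   per drug; no event-type taxonomy.
5. **Switching** — any relapse, EDSS progression or adverse event moves
   the patient one line onward. An adverse event on line 1a diverts to
   the alternative first-line drug (line 1b) when the sequence has one;
   in a sequence opened by a high-efficacy drug line 1b is dropped.
   Relapses on line 1b advance to line 2 exactly as from 1a (the model
   makes no distinction). Past the final line the patient follows
   untreated natural history; there is no re-initiation.
6. **Discontinuation** — patients aged ≥ 50 with ≥ 5 years free of
   relapse and progression on lines 1a/1b/2, or aged ≥ 70 with ≥ 10
   event-free years on line 3, stop treatment permanently. The
   event-free clock counts relapses and progression only (not adverse
   events) and is *not* reset by treatment switches; whether it should
   be measured per drug instead is a natural sensitivity analysis.

Survivors are administratively censored at age 100, the end of the life
table.

### Accrual and outcomes

Costs accrue per cycle on the state occupied during the cycle (no
half-cycle correction — a known small bias, accepted for transparency):
drug acquisition (first-year versus subsequent-years price),
administration and monitoring while on treatment, EDSS-state healthcare
costs, a one-off cost per relapse, and EDSS-state societal costs
(productivity loss, caregiver time). Utilities are EDSS-state weights
minus a per-relapse decrement; a cycle's QALY may go below zero after
many relapses (decrements are additive, not floored). Costs are
discounted at 4%/yr and effects at 1.5%/yr (Dutch guideline; both
configurable), with cycle 0 undiscounted.

A cohort result reports mean discounted costs by category, mean
discounted QALYs, lifetime relapses, time to EDSS 6 — averaged over the
patients who reach it, always flanked by the fraction reaching it to
avoid survivorship misreadings — time in line 1, life years, and the net
health benefit `NHB = QALYs − costs/λ` at λ = €50,000 per QALY. Reported
NHB comes from unrounded internals, so a table's NHB row can differ in
the last digit from what its rounded cost and QALY rows would give.

### Randomness and common random numbers

Every patient owns an independent uniform substream derived from
`(seed, patient index)`, five numbers per cycle: death, relapse count,
progression occurrence, transition severity, adverse event. Two design
choices matter:

- the relapse count is the Poisson *quantile* of its uniform, and "any
  worsening" occurs when the progression uniform exceeds `1 − p'` —
  both are monotone in the treatment effect for a fixed draw;
- progression *occurrence* and transition *severity* use separate
  uniforms, so the treatment effect never re-maps which higher state a
  worsening patient lands in.

Cohorts simulated under different sequences, prices or effect sizes with
the same `n` and seed therefore reuse identical draws. This makes paired
comparisons nearly noise-free, underpins the monotonicity properties the
test suite asserts (lower price ⇒ higher NHB, exactly; lower RR ⇒ no
shorter time to EDSS 6; lower IRR ⇒ no more relapses, at cohort level),
and defines NHB parity in the threshold searches.

## Input parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| Cohort size | patients | 10,000 | study design; scale down for speed |
| Start age / baseline EDSS | years / states | 29, round-robin over 0–3 | treatment-naive diagnosis cohort ("EDSS class 0 to 3" is read as integer points) |
| Discount rates | /yr | 4% costs, 1.5% effects | Dutch guideline |
| Willingness-to-pay λ | €/QALY | 50,000 | Dutch MS threshold |
| Utility at EDSS 2 | – | 0.782 | published anchor of the utility set |
| IRR, RR per DMT | ratio | published table via `table1_defaults()` | network-meta-analysis inputs, consumed as printed |
| Rituximab RR of CDP | ratio | unknown sentinel | its trial was not powered for CDP; an explicit sentinel (not 1.0) so deterministic runs refuse it until the threshold analysis supplies a trial value |
| PSA design | – | 500 iterations × 1,000 patients | study design |
| Threshold tolerance | QALY | 0.005 | below the Monte-Carlo scale that common random numbers leave in an NHB difference |

Drug list prices are integer Euros; accrued totals stay real and are
rounded to integer Euros only in reports.

## The synthetic parameter generator

The underlying Dutch natural-history, utility and cost inputs are not
published as data, so `generate_synthetic_params()` builds a complete
stand-in that reproduces their *structure*: strictly decreasing utilities
through the 0.782 anchor at EDSS 2; healthcare and societal costs rising
roughly 30-fold and 25-fold from EDSS 0 to 9; forward-dominated annual
transitions (worsening mass 2–15% per state, split 70/20/10 over one-,
two- and three-step jumps; improvement ≤ 3%); relapse rates declining
from about 0.7 to 0.3 per year with disability; Gompertz background
mortality (`2.5e-5 · exp(0.085 · age)`); and non-decreasing EDSS
mortality multipliers anchored at 1. The published anti-CD20 efficacy
and price inputs enter verbatim; the other ten DMTs carry filler
efficacy ordered by class plausibility (platform < moderate < high
efficacy) and are flagged `synthetic = TRUE` in serialized output so
they cannot be mistaken for published values. Scenario scale factors
(progression, relapse, cost intensity) move the whole structure up or
down; seeds perturb the matrices a few percent.

What passing tests show — and don't. The suite demonstrates that the
engine is correct against a deterministic Markov-cohort oracle, that
simulated effect sizes are recoverable by regression from the simulated
cycles, and that the economic layer's arithmetic matches the published
worked examples. It does *not* show that the synthetic world reproduces
published cohort magnitudes: lifetime relapse counts, for instance, run
far above published sequence models because the generator ties relapse
rates to EDSS only, with no separate age decline; time in line 1 is
correspondingly short. `calibration_report()` flags (without failing)
whether treated time to EDSS 6 falls in a plausibility envelope of
15–35 years, bracketing published sequence-model values.

## Sequence grammar

Sequences are chains over lines 1a, 2, 3, 4 plus an optional line-1b
branch. The default rule set encodes: escalation openers (interferon,
fumarate, teriflunomide, glatiramer and the S1PR modulators) versus
high-efficacy openers (the anti-CD20s); no consecutive drugs of the same
mode of action (no anti-CD20 after anti-CD20); alemtuzumab only in the
final line; no re-treatment with a drug already used. Enumeration is
exhaustive and lexicographic, verified against brute-force filtered
permutations on universes of up to six drugs. The exact Dutch
eligibility table that yields the published count of 144 second-line
sequences per anti-CD20 is not printed anywhere; the shipped rule set is
a documented reconstruction and the package *reports* its own count
rather than asserting one.

## Probabilistic sensitivity analysis

Each iteration draws one joint input set — lognormal treatment-effect
ratios whose median and 95% interval match the published point and CI
(`σ = (ln hi − ln lo)/3.92`), beta utilities and gamma state costs and
relapse rates moment-matched from the point value and a coefficient of
variation (defaults 5%, 15%, 15%; configurable in the `psa` section) —
and runs both arms under that draw with common random numbers. Sampling
can break the monotonicity invariants a valid parameter set must
satisfy, so sampled utilities are restored with a running minimum and
costs with a running maximum. The transition matrix, relapse cost and
relapse disutility stay fixed across draws: progression uncertainty is
carried by the RR intervals, and the source material specifies sampling
"from the confidence intervals" only. Probabilities of cost-effectiveness
are reported with binomial standard errors and count exact ties as one
half (so a self-comparison reports 0.5, not 1.0).

## Threshold searches

Both searches bisect until the candidate sequence's NHB is within
0.005 QALYs of the reference NHB, computed with the same seed and cohort
size. Price: NHB is exactly affine in price under common random numbers
(trajectories don't depend on price), so bisection on [0, 2 × the
reference drug's price] converges cleanly; the solved price is also
reported rounded to the nearest €100, the reporting convention for such
thresholds. A candidate with a known cost schedule keeps its first-year/
subsequent-year ratio as the price scales ("proportional"); a drug with
no schedule gets a flat price. Relative risk: bisection on [0.2, 1.2];
NHB is non-increasing in RR under shared draws, and the result is
reported to two decimals. Rituximab's two dose formulations share one
pooled IRR — only their prices differ — since only one pooled relapse
estimate is published. A bracket without an NHB sign change raises an
error carrying the search trace.

## Numerical choices and degenerate inputs

- Transition sampling clamps the selected state index at the top state
  to absorb floating-point edge cases in the cumulative row.
- Zero worsening mass means no progression regardless of RR; a zero
  base rate yields zero relapses for any IRR.
- Sequences using a drug with unknown progression efficacy or unknown
  price refuse to simulate, with an error directing to `set_dmt_rr()`,
  `set_dmt_cost()` or the threshold analysis.
- If both a relapse and an adverse event occur on line 1a of an
  escalation sequence, the adverse-event routing to line 1b wins.
- Patient substream seeds are reduced modulo 2^31 − 1; iteration seeds
  in the PSA are derived as `(seed mod 10^6)·1000 + k`.

## Problem sizes used in the shipped checks

The test suite and the acceptance script scale the study design down to
sizes chosen for quick, repeatable runs while keeping Monte-Carlo
standard errors far below the asserted tolerances: 10,000 patients where
a statistical oracle or effect recovery is checked, 2,000–5,000 for
deterministic comparisons, 800–1,500 for threshold searches (parity is
seed-paired, so its precision does not depend on n), and 15–100
iterations of 150–250 patients for the PSA null and calibration checks,
with the 500-draw binomial checks run on synthetic difference samples.

## Known limitations

- No treatment-effect waning, no monthly cycles, no adverse-event
  taxonomy, no re-treatment, and no secondary-progressive conversion —
  progression is entirely EDSS-transition driven.
- Relapse rates depend on EDSS but not directly on age or time since
  onset; lifetime relapse counts are correspondingly high.
- No half-cycle correction.
- The within-cycle event order is fixed; outcomes are conditional on it.
- Combined-by-drug columns average sequence means (each sequence equally
  likely), which equals the pooled-patient mean only for equal cohort
  sizes.
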