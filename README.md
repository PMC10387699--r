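# dmtseq

Treatment-sequence health-economic microsimulation for relapsing multiple
sclerosis (MS).

People with relapsing MS rarely stay on one disease-modifying treatment
(DMT): they switch after relapses, disability progression or adverse
events, through sequences of up to five treatment lines. Whether one drug
in a class — here the anti-CD20 monoclonal antibodies ocrelizumab (OCR),
ofatumumab (OFA), ublituximab (UBL) and off-label rituximab (RIT) — is
worth its list price therefore depends on the whole lifetime sequence it
sits in, not on a single head-to-head comparison. `dmtseq` is aimed at
health-economic modellers and clinical researchers who want to compare
such sequences, price a new entrant, or ask how effective a cheap
off-label drug would have to be to compete.

## What it computes

The engine simulates individual patients in annual cycles from diagnosis
(age 29, EDSS 0–3) until death. Each cycle draws, in fixed order: death
(life-table hazard × an EDSS-dependent multiplier), relapses (Poisson with
rate `ARR(EDSS) × IRR`), EDSS transition (the annual worsening probability
`p` scaled to `1 − (1 − p)^RR`), and adverse events. Any relapse, EDSS
progression or adverse event moves the patient one treatment line onward
(adverse events on line 1a divert to the alternative first-line drug 1b);
stable older patients discontinue treatment per clinical stopping rules.

Costs (drug, other healthcare, societal; discounted at 4%/yr) and
quality-adjusted life years (EDSS-state utilities minus relapse
decrements; discounted at 1.5%/yr) accrue per cycle. Sequences are
compared by **net health benefit**,

    NHB = QALYs − costs / λ,      λ = €50,000 per QALY,

so a sequence's extra QALYs are weighed against the QALYs its costs could
buy elsewhere. On top of the engine sit:

- a **sequence grammar** that enumerates clinically plausible sequences
  (line eligibility, no consecutive same mode of action, alemtuzumab only
  as last resort);
- **probabilistic sensitivity analysis**: joint draws from the input
  uncertainty (lognormal ratios from the published CIs, beta utilities,
  gamma costs), both arms run with common random numbers;
- **threshold searches**: the annual price at which a candidate drug's
  sequence reaches NHB parity with a reference sequence (NHB is exactly
  affine in price), and the relative risk of disability progression a
  drug with unknown progression efficacy would need at its known price;
- a **synthetic parameter generator** producing a complete, internally
  consistent input set (utilities anchored at 0.782 for EDSS 2, costs
  rising with EDSS, forward-dominated transitions, Gompertz mortality),
  so every stage runs without access to the original Dutch model inputs.

## Worked example

```r
library(dmtseq)

params <- generate_synthetic_params(scenario_spec(seed = 1))
seqs <- list(sequence_spec(c("OCR", "CLA", "NAT", "ALE")),
             sequence_spec(c("OFA", "CLA", "NAT", "ALE")))
compare_sequences(params, seqs, n = 2000, seed = 1)
```

```
Mean cost-effectiveness outcomes (n = 2000 per sequence, seed = 1)
                               OCR-CLA-NAT-ALE OFA-CLA-NAT-ALE
Total costs (Euros)            653,551         654,317
Drug costs (Euros)             190,099         192,058
Other healthcare costs (Euros) 293,411         290,841
Societal costs (Euros)         170,041         171,418
Total QALYs                      21.13           21.08
NHB                               8.05            7.99
Lifetime relapses                20.70           20.20
Time to EDSS 6 (years)           29.86           29.69
Time in line 1 (years)            3.53            4.07
```

Both cohorts share random draws, so the differences are treatment-driven:
the ocrelizumab-first sequence gains about 0.05 QALYs (its stronger effect
on disability progression outweighs ofatumumab's better relapse
prevention) at near-equal total cost, giving it the slightly higher net
health benefit. Because the natural-history, utility and cost inputs are
synthetic emulations, the absolute magnitudes are illustrative; the
published anti-CD20 efficacy and Dutch price inputs are available
verbatim via `table1_defaults()`.

Other entry points: `run_psa()` (+ `plot()` for the cost-effectiveness
plane), `find_threshold_price()`, `find_threshold_rr()`,
`enumerate_sequences()`, `calibration_report()`, and a small CLI
(`inst/cli/dmtseq.R` or `dmtseq_main()`). The methods vignette
(`vignettes/treatment-sequence-model.Rmd`) documents the model,
its assumptions and its limitations.

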