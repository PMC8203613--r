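# pvsignal

Disproportionality signal detection for spontaneous adverse-event reports.

`pvsignal` is an R package for pharmacovigilance data mining on FAERS-style
relational report tables (the FDA Adverse Event Reporting System quarterly
layout: demographics, drugs with role codes, reactions coded as MedDRA
preferred terms, outcomes). It is aimed at drug-safety analysts and
methodologists who need a reproducible, testable pipeline from raw report
tables to a screened signal list — including a synthetic-data generator with
known ground truth, so every stage can be validated without access to the
real database or the licensed MedDRA dictionary.

## What it computes

For a target drug *D* and an adverse event term *E* (at the PT, narrow-SMQ
or SOC level), the deduplicated reports (or (report, PT) pairs, the default
counting unit) are cross-classified as

|                | target event | all other events |
|----------------|--------------|------------------|
| target drug    | a            | b                |
| other drugs    | c            | d                |

with N = a + b + c + d, and three classical statistics are evaluated:

- **ROR** (reporting odds ratio): `ROR = (a·d)/(b·c)`, with the Wald 95% CI
  `exp(ln ROR ± 1.96·√(1/a + 1/b + 1/c + 1/d))`. Positive when the CI lower
  bound exceeds 1 and a ≥ 3.
- **PRR** (proportional reporting ratio): `PRR = (a/(a+b)) / (c/(c+d))`
  with Pearson's `χ² = N(ad−bc)² / ((a+b)(c+d)(a+c)(b+d))` (optional Yates
  correction). Positive when PRR ≥ 2, χ² ≥ 4 and a ≥ 3.
- **BCPNN IC** (Bayesian confidence propagation neural network information
  component): the raw component is `IC = log₂(a·N/((a+b)(a+c)))`; the
  reported value uses the closed-form Bayesian posterior approximation with
  priors α₁ = β₁ = γ₁₁ = 1, α = β = 2, which shrinks small counts towards
  independence. Positive when IC − 2SD > 0.

A **suspicious signal** is declared only when all three algorithms are
positive — the conservative triple rule used throughout the package. A zero
cell triggers the Haldane–Anscombe correction (0.5 added to all four cells)
for ROR/PRR/χ²; the Bayesian IC needs none.

## Worked example

```r
library(pvsignal)

# Simulate a small FAERS-like database with one injected association:
# "drug_a" multiplies the background rate of acute pancreatitis by 8.
cfg <- simulation_config(
  30000,
  associations = data.frame(drug = "drug_a", pt = "Pancreatitis acute",
                            rr = 8),
  seed = 42)
sim <- generate_reports(cfg)
reports <- deduplicate(sim$reports)   # one report per case (latest version)

dict <- load_dictionary(pvsignal_dictionary())
screen <- run_screen(reports, drug_query("drug_a"), level = "pt",
                     dict = dict)
print(screen, n_show = 3)
```

```
<faers_screen> drug_a @ pt level, pair unit; 40 terms, 1 combined-positive
                  term    N      ROR (95%CI)     PRR (chi2)   IC (IC-2SD) signal
    Pancreatitis acute 5047 6.31 (5.90-6.76) 5.55 (3510.93)   0.83 (0.78)    yes
 Hepatocellular injury  843 0.98 (0.89-1.08)    0.98 (0.18) -0.02 (-0.14)     no
          Palpitations  832 0.96 (0.88-1.06)    0.96 (0.62) -0.03 (-0.15)     no
... and 37 more terms
```

The injected pair is the single combined-positive row: the ROR of 6.3
estimates the injected relative risk (attenuated below 8 because the event
is common here — the odds ratio only approximates the rate ratio for rare
events, and a weight multiplied eightfold stops being rare), the PRR and χ²
clear their thresholds, and the shrunken IC − 2SD is above 0. Every other
term stays negative.

```r
dispro(build_table(reports, "drug_a", "Pancreatitis acute", "pt"))
#> N = 5047 | ROR 6.31 (5.90-6.76) | PRR 5.55 (3510.93) | IC 0.83 (0.78)
#> <signal_evaluation> N = 5047; ROR+ PRR+ IC+ => SIGNAL

descriptive_summary(reports)   # report counts, events/report, SAE share...
```

The same functions ingest real extracts: `read_faers_tables()` (comma or
`$`-delimited dialects) → `assemble_reports()` → `deduplicate()` →
`filter_suspect()` / `filter_completeness()` / `filter_period()` →
`run_screen()`.

## Scope notes

The bundled dictionary is a synthetic MedDRA-like fixture (40 PTs, 8 SOCs,
5 narrow SMQs); the licensed MedDRA dictionary is not included, but any
dictionary in the documented two-section CSV format can be supplied.
Downloading FAERS itself is out of scope. See the methods vignette
(`vignettes/disproportionality-screening.Rmd`) for the statistical model,
design decisions and limitations.
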