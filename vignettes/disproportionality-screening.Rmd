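---
title: "Disproportionality screening of spontaneous adverse-event reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality screening of spontaneous adverse-event reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spontaneous reporting systems such as FAERS collect post-marketing case
reports: a patient, one or more suspect and concomitant drugs, one or more
adverse reactions coded as MedDRA preferred terms (PTs), and outcome codes.
There is no denominator — nobody knows how many patients took the drug
without an event — so safety signals are sought by *disproportionality*:
does drug D appear together with event E more often than the rest of the
database would predict? `pvsignal` implements that pipeline end to end,
from raw relational tables to a screened signal list, with a synthetic
generator so the whole chain is testable against known ground truth.

## From raw tables to analysable reports

`read_faers_tables()` reads the four quarterly-ASCII style tables (comma or
`$`-delimited). `assemble_reports()` joins them into one report per
`primaryid`, collapses repeated PTs within a report to set semantics,
drops reports with no reaction, excludes orphan rows, converts ages to
years (`DEC` ×10, `YR` ×1, `MON` ÷12, `WK` ÷52, `DY` ÷365, `HR` ÷8760 —
the FAERS `age_cod` conventions) and bins them (<18, 18–44, 45–64, 65–74,
≥75, unknown). Every drop is counted, and the counts satisfy an exact
conservation law (kept pairs + collapsed duplicates + orphans = input
rows) that the tests verify.

Cases are resubmitted as new versions under one `caseid`.
`deduplicate()` keeps, per case, the version with the greatest FDA date,
breaking date ties by the greatest `primaryid` (numeric comparison where
ids are numeric). This reading follows the FDA's deduplication
recommendation; it is idempotent and order-deterministic (output sorted by
case id), which is what makes byte-identical reruns possible. Screens and
summaries *refuse* input whose provenance lacks the deduplication step —
version inflation is the classic way to overcount.

Three row filters follow: `filter_suspect()` keeps reports where the query
drug has role PS or SS (a drug present only as concomitant or interacting
does not qualify the report); `filter_completeness()` removes reports with
strictly more than `max_missing` (default 3) missing items over an audited
field set (sex, age, reporter occupation, FDA date, outcomes, plus country
and weight when present — the set is configurable and recorded in
provenance); `filter_period()` applies a closed `[start, end]` interval on
the FDA date. The FDA date (not the event date) is used because it is the
field the deduplication rule is defined on and the one reliably populated.
A published exclusion of records "with more than three differences" admits
two readings — a near-duplicate heuristic across field differences, or the
missing-information rule; only the completeness reading is implemented, as
the other is underdetermined (no field list or comparison order exists to
define it).

## The 2×2 table and its counting unit

For a (drug, term, level) triple, `build_table()` cross-classifies the
database into the cells a (target drug & target event), b (target drug &
other events), c, d. Two counting units are supported:

* **pair** (default): the unit is the (report, distinct PT) pair, and at
  SOC/SMQ level each pair is classified by its own PT. Cells then sum
  exactly to the total pair count, giving an exact conservation invariant
  (Σ of a over all PTs = total target pairs) that the tests exploit.
  The pair unit is the natural reading when a database's event total
  exceeds its report total (≈2.5 events per report).
* **report**: a report counts in a when *any* of its PTs matches. Pair-a ≥
  report-a always holds (a matching report contributes at least one
  matching pair).

Reports where the target drug appears only in non-suspect roles are kept in
the "other drugs" stratum: the suspect-role rule defines inclusion in the
target stratum only, and the comparator is the whole remaining database
(standard practice when the background is not restricted to a drug class).

## The three statistics

With N = a+b+c+d:

* **ROR** = ad/bc, 95% CI `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`.
* **PRR** = (a/(a+b)) / (c/(c+d)) — the event's share among the target
  drug's pairs over its share among everyone else's. Some published tables
  print the column-wise variant (a/(a+c))/(b/(b+d)); it is available via
  `orientation = "column"`, but the row-wise form is the default because it
  is the standard definition relative to the drug-by-event table
  orientation. `χ² = N(ad−bc)²/((a+b)(c+d)(a+c)(b+d))`, Pearson without
  continuity correction by default (`yates = TRUE` replaces |ad−bc| by
  max(|ad−bc|−N/2, 0)).
* **BCPNN IC**: the raw information component is
  log₂(aN/((a+b)(a+c))). The reported IC and its SD use the closed-form
  posterior approximation with the conventional priors α₁ = β₁ = γ₁₁ = 1,
  α = β = 2 and γ = γ₁₁(N+α)(N+β)/((a+b+α₁)(a+c+β₁)):

  IC = log₂[(a+γ₁₁)(N+α)(N+β) / ((N+γ)(a+b+α₁)(a+c+β₁))],

  with variance
  (1/ln2)²·[(N−a+γ−γ₁₁)/((a+γ₁₁)(1+N+γ)) +
  (N−(a+b)+α−α₁)/((a+b+α₁)(1+N+α)) + (N−(a+c)+β−β₁)/((a+c+β₁)(1+N+β))].
  The shrinkage pulls small counts towards independence: the posterior IC
  always lies between 0 and the raw IC for a positive-association table,
  and converges to the raw IC as all cells grow (tested at ×1, ×10, ×100,
  ×1000). "IC−2SD > 0" is the signal criterion; the raw IC is also
  reported for transparency.

Useful identities, property-tested on random tables: sign(ROR−1) =
sign(PRR−1) = sign(raw IC), and ROR/PRR = (a+b)d/(b(c+d)), so
ROR > PRR > 1 whenever ad > bc.

**Zero cells.** With the default `haldane-on-zero` policy, 0.5 is added to
all four cells if and only if some cell is zero, for ROR/PRR/χ² only; with
`correction = "none"` a zero cell is an error. The Bayesian IC is finite
for a = 0 (the raw IC is −∞ and reported as such).

**Signal rule.** `evaluate_signal()` requires ROR CI lower bound > 1, PRR ≥
2 with χ² ≥ 4, IC−2SD > 0, and a ≥ `min_n` (default 3); below `min_n` all
flags are forced negative. The combined verdict is the conjunction. No
multiple-testing correction is applied anywhere: disproportionality
screens conventionally rely on the triple-positivity conjunction as their
only stringency mechanism, and the null calibration below quantifies what
that buys. Thresholds are user-configurable via `signal_criteria()` or a
YAML file (`read_screen_config()`).

All statistics are computed at full precision; two-decimal rounding
(half-up, matching how published tables round) is confined to the
presentation layer (`print` methods, `write_screen(digits = 2)`).

## Term aggregation

A `term_dictionary` maps each PT to exactly one SOC and defines narrow SMQ
membership sets. Only narrow scope is modelled: narrow SMQs are the
high-specificity sets screens are usually run on, and broad scope would
require graded membership the file format does not carry. Lookups are
case-insensitive on whitespace-normalised names. PTs absent from the
dictionary are retained for PT-level screens and reported as unmapped
(verbatim FAERS terms often lag dictionary versions), but never match at
SOC/SMQ level. The bundled dictionary (40 PTs, 8 SOCs, 5 narrow SMQs) is a
synthetic fixture with realistic spellings — it is not an extract of the
licensed MedDRA dictionary, and real analyses should supply their own file
in the documented two-section CSV format.

A pregnancy-type subgroup screen needs no separate machinery: it is
`run_screen()` on the PTs mapping to the relevant SOC, because the
statistics are identical on any term subset. Per-drug comparisons
(`run_drug_comparison()`) screen each named query over a fixed PT list,
emitting n = 0 negative rows for absent terms so the outputs stay aligned.

## The synthetic generator

`generate_reports()` draws, per case: suspect drugs independently with
per-drug prevalences (at least one enforced by a probability-weighted
fallback); an event count from a zero-truncated Poisson; PTs by background
weights, with the weight of an associated PT multiplied by the injected
relative risk when its drug is suspect; a duplicate case version with
probability `duplicate_rate` (same case id, FDA date +1..90 days — built
to exercise the deduplication rule); and per-field MCAR missingness.
Everything is reproducible from one seed, and the output goes through the
same `assemble_reports()` path as real files (round-trip through both file
dialects is tested).

Default parameters are chosen once to emulate a darunavir-like report
series: mean 2.53 distinct events per report (the published average), sex
split ≈65/35 among known, age unknown ≈42% and sex unknown ≈17% (the
published unknown shares), hospitalisation ≈33% — so that descriptive
summaries of synthetic data look like the real series they imitate. The
drug vocabulary defaults to eight drugs with prevalences from 20% down to
1%.

One calibration detail matters: PTs within a report are collapsed to a
set, so repeated draws of the same PT shrink the *observed* distinct-event
mean below the raw Poisson mean. The Poisson rate λ is therefore
calibrated by solving Σⱼ P(PT j appears) = target mean, where
P(PT j appears) = 1 − E[(1−qⱼ)^K] under K ~ ZTP(λ) — so the configured
`mean_events_per_report` is the mean of what the pipeline actually counts,
for any vocabulary size.

`expected_table()` gives the closed-form expected pair counts under the
same model (enumerating exposure patterns of the associated drugs), used
as the recovery oracle. Because association weights renormalise within a
report, the expected ROR for an injected relative risk ρ on a rare event
is ρ/(1 + q(ρ−1)) with q the event's weight share — ≈3.97 for ρ = 4 at
q = 0.002 — which is what "ROR approximates RR for rare events" means
quantitatively here. The generator does not model reporting biases
(Weber-type time trends, stimulated reporting, masking by co-reported
drugs), reporter-dependent coding error, or correlated missingness; a
passing recovery study therefore shows the *statistics and pipeline* are
sound, not that real FAERS extracts are free of those biases.

## Validation summary

The test suite and `scripts/acceptance.R` recompute, at these problem
sizes (chosen to keep a full run in minutes on one core):

* descriptive arithmetic on a fixture with the published marginal counts
  of the darunavir series (10,756 reports, 27,234 events): events/report
  2.53, male 54.47%, ages 18–60 49.31%, serious outcomes 41.47%,
  hospitalisation 32.57%, life-threatening 4.89%;
* agreement of all three statistics with an independently written
  closed-form oracle to 10⁻¹⁰ on 1,000 random tables (χ² cross-checked
  against `chisq.test`);
* null calibration: 20 synthetic databases of 20,000 reports × 200 PTs
  with no injected association — the combined-positive rate stays below
  5% (observed ≈0), and the ROR 95% CI covers the true odds ratio 1 in
  94–96% of 2,000 multinomial draws;
* recovery: injected relative risk 4 on a rare event (weight 0.002, drug
  prevalence 1%) in 20 databases of 200,000 reports — detection rate
  ≥95% and mean estimated ROR within [3.2, 4.8] of the truth.

## Known limitations

* Disproportionality measures reporting, not risk: a positive signal is a
  reporting association, never a causal or incidence statement.
* The near-duplicate "more than three differences" exclusion is not
  implemented (see above); only exact case-version deduplication is.
* No HLT/HLGT intermediate MedDRA levels, no broad-scope SMQs, no MedDRA
  version migration.
* No EBGM/MGPS empirical-Bayes shrinkage, sequence-symmetry or
  time-to-onset methods; the three implemented statistics are the classic
  frequentist/BCPNN trio.
* The Wald ROR interval undercovers for very small cells even with the
  Haldane correction; the `min_n` criterion is the guard rail.
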