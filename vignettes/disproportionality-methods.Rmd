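---
title: "Disproportionality signal detection on spontaneous-report data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection on spontaneous-report data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous adverse-event reporting systems such as the FDA Adverse
Event Reporting System (FAERS) collect safety reports for all marketed
drugs. Because there is no denominator of exposed patients,
pharmacovigilance screens these databases with *disproportionality
analysis*: for a drug of interest (here, the low molecular weight
heparins: enoxaparin, nadroparin, dalteparin, tinzaparin, bemiparin,
reviparin, parnaparin) and each adverse-event term, one asks whether the
pair is reported more often than expected given the margins of a 2×2
contingency table

|                 | target term | other terms |
|-----------------|-------------|-------------|
| target drug     | a           | b           |
| all other drugs | c           | d           |

built over a stratum of reports (the whole database, or a subgroup such
as pregnancy-related reports). `faersignal` implements the full pipeline
around this table: ingestion of the FAERS quarterly ASCII dialect,
case-version deduplication, drug-name normalization, SMQ-based
pregnancy-cohort retrieval, event-level tabulation, four estimators
with a combined signal criterion, descriptive summaries, and a
synthetic-data generator that makes the whole chain testable offline.

## Counting unit

All statistics are computed on *events*, defined as distinct
(report, preferred term) pairs: a report listing three distinct reaction
PTs contributes three events to the grand total `N`. This choice is
validated empirically: the published marginals for the heparin analysis
(61,949 target events among 52,373,206 overall; 7,840 among 1,279,728 in
the pregnancy stratum) reproduce every printed statistic exactly once
the 2×2 tables are reconstructed (see `validate_reference_rows()`).
System-organ-class (SOC) counts sum the events of their member PTs
without per-report collapsing, which conserves `N`. The comparator is
always "all other drugs in the same stratum", so pregnancy signals are
judged against the pregnancy background — subgroup disproportionality
avoids the bias of judging pregnancy outcomes against a mostly
non-pregnant reporting population.

## Estimators

With `N = a+b+c+d`, `faersignal` computes:

* **ROR** `= ad/bc`, with 95% bounds
  `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`;
* **PRR** `= [a/(a+b)]/[c/(c+d)]`, bounds
  `exp(ln PRR ± 1.96·√(1/a − 1/(a+b) + 1/c − 1/(c+d)))`, accompanied by
  the Pearson chi-square `N(ad−bc)²/[(a+b)(c+d)(a+c)(b+d)]` *without*
  Yates continuity correction;
* **IC** `= log₂(aN/((a+b)(a+c)))` — the information component, the
  base-2 log of the observed/expected ratio — with **IC025** the BCPNN
  posterior expectation minus two posterior standard deviations under
  the prior constants `γ₁₁ = α₁ = β₁ = 1`, `α = β = 2` and the per-table
  joint prior count `γ = γ₁₁(N+α)(N+β)/((a+b+α₁)(a+c+β₁))` ("IC − 2SD");
* **EBGM** `= aN/((a+b)(a+c))` — the observed/expected ratio, carrying
  the conventional signal-table label — with
  `EBGM05 = exp(ln EBGM − 1.96·√(1/a+1/b+1/c+1/d))`.

Two deliberate hybrids deserve a note. First, the IC *point* estimate is
the unshrunk `log₂(O/E)` while IC025 uses the Bate posterior; this pair
is what reproduces both printed columns of the reference rows (four or
more rows per stratum validate each). Second, "EBGM" here is the plain
O/E ratio: no DuMouchel gamma-mixture (MGPS) hyperparameter fit is
applied. The published values force this reading (e.g.
317.03 = 6·52,373,206/(61,949·16)); full MGPS shrinkage and
MCMC-based IC posteriors are out of scope, and small-count estimates are
therefore *not* shrunk — a known limitation to keep in mind for cells
with `a` near the minimum.

Exact identities the test suite enforces: `IC = log₂(EBGM)` on every
defined table; independence margins give ROR = PRR = EBGM = 1, IC = 0,
χ² = 0; all four estimators are strictly increasing in `a` at fixed
margins; the chi-square agrees with Σ(O−E)²/E to 1e−9 relative.

### Degenerate tables

Any zero cell leaves all statistics undefined (`NA`); no Haldane 0.5
correction is applied. An undefined statistic can never satisfy its
criterion, and the minimum-count rule (`a ≥ 3`) makes such rows
non-signals regardless. No multiple-testing adjustment is applied —
conventional in this analysis style, and a documented limitation.

## The combined signal criterion

A (drug, term) pair is a *signal* when all six hold: `a ≥ 3`, lower ROR
bound > 1, `PRR ≥ 2`, `χ² ≥ 4`, `IC025 > 0`, `EBGM05 > 2`. The
conjunction is strict: on null (relative risk 1) synthetic data the
empirical flag rate over pairs with `a ≥ 3` stays below 1%. Signals are
ranked by descending ROR, ties broken by `a` then term name. Thresholds
are configurable via `signal_criteria()`.

## Reconstructing published rows

`reconstruct_table()` inverts a printed table row: given `a`, the
stratum marginals and the printed ROR, the comparator cell is
`c = round((N − drug_total)/(1 + ROR·(drug_total − a)/a))`, and the
reconstruction is accepted only if the recomputed ROR rounds (2 dp) back
to the anchor. For small `c` this inversion is unique (a brute-force
scan over `c` confirms it in the tests); rows with large `c` — the SOC
rows and the highest-count PT rows — admit a range of `c` values that
all round to the same ROR, so they cannot be pinned exactly and are not
in the shipped fixture. The 15 rows of `reference_rows()` are exactly
recoverable and every one reproduces all printed statistics at
2-decimal rounding (interval bounds at 3 significant digits: published
interval bounds wobble in the 4th–5th significant digit, presumably
from intermediate rounding upstream).

## Ingestion and deduplication

The quarterly ASCII dialect is "$"-delimited with one header row per
file. The reader tolerates extra columns, maps era-specific column
aliases, treats empty fields as missing, skips malformed rows with a
counter, and fails hard on a missing required column. Deduplication is
per *case*: FAERS re-submits revised versions of a case under new
`primaryid`s, so exactly one record per `caseid` is retained — the
latest receipt date, ties broken by the largest `primaryid` (the
standard practice; the version identifier is monotone in submission
order). Deduplication precedes all filtering. Age is harmonized to
years from the unit codes (YR, DEC, MON, WK, DY, HR) with fixed
divisors; dates must be full 8-digit values for onset arithmetic, while
partial dates still contribute their year to annual tallies. Reported
country prefers the occurrence country and falls back to the reporter
country.

## Pregnancy cohort retrieval

Reports are retrieved when their *reactions* intersect the member PTs
of six pregnancy SMQs (codes 20000077, 20000186, 20000190, 20000191,
20000192, 20000193) or their *indications* intersect three of them
(20000186, 20000190, 20000193). Retrieved reports are then partitioned:

* **definitive** — a maternal/foetal exposure PT (e.g. 10071408,
  "maternal exposure during pregnancy") among reactions or indications,
  or a transplacental administration route;
* **excluded** — a paternal-exposure PT (e.g. 10050425), or a pediatric
  age, or (optionally) male sex;
* **other** — SMQ evidence only;

and the cohort is the union of definitive and other, each report counted
once even when both retrieval routes hit it. Three open policy choices
are encoded as configuration with these defaults:

* *Pediatric cutoff*: below 12 years an SMQ-retrieved report is treated
  as a pediatric-treatment report and excluded. No authoritative age is
  available; 12 is a conservative lower bound for potential pregnancy
  and is a visible, documented knob.
* *Male sex*: retained and annotated (`ineligible_demographics` in the
  reasons), not excluded — published characteristics tables keep male
  rows tabulated while footnoting them as misreporting; a switch flips
  to exclusion.
* *Precedence*: all exclusion rules are evaluated before the
  definitive/other split, and definitive evidence never rescues an
  excluded report (in particular, paternal exclusion beats a definitive
  PT). Every rule that fired is recorded, so alternative policies can be
  audited from the label table alone.

Since MedDRA and SMQ content are licensed, the package ships no member
lists: SMQ membership is user-supplied configuration, and the test
fixtures use synthetic dictionaries that combine the literal published
codes with invented filler terms.

## The synthetic generator

`generate_faers()` emits a complete six-table bundle plus a manifest of
ground truth. What it emulates, chosen to mirror the structure the
pipeline must survive: heavy-tailed PT marginals (Zipf, exponent 1.2
over 200 generic terms), multi-PT reports (`max(1, Poisson(2.5))`
selections per report, duplicates collapsing), one primary-suspect drug
per case with brand/case-variant naming, planted (drug, PT) relative
risks (per-selection odds multiplied and renormalized for target-drug
cases), pregnancy subcohorts with event-SMQ and/or indication-SMQ
evidence and a definitive fraction (half via exposure PTs, half via
transplacental route), paternal-exposure plants that must be retrieved
and then excluded, duplicate case versions (older receipt date, smaller
`primaryid`), and plausible demographics, outcomes and therapy dates.
Default shares: 2% target-drug cases, 5% pregnancy, 0.5% paternal, 3%
duplicate versions — desk-scale choices that keep every code path
populated at a few thousand cases.

What it does *not* emulate: co-prescription correlation, temporal
reporting trends, free-text misspellings beyond case/punctuation
variants, and reporting biases (stimulated reporting, masking). Passing
recovery tests therefore demonstrates correctness of the pipeline's
logic under a clean generative model, not robustness to real-world
reporting pathology.

`expected_signal_counts()` gives the closed-form expected target count
for each planted signal (`P(PT in report) = 1 − e^(−λp) + p·e^(−λ)`),
which is how test scenarios are sized: the end-to-end recovery tests
plant a relative risk of 20 on the rarest vocabulary PT so that the
expected target count is ≈ 45 at 100,000 cases, and verify detection
across 20 seeds with the EBGM within a factor of two of truth (the O/E
estimator is biased slightly below the true relative risk because the
term margin includes the boosted target events — visible in the tests
and expected). Null calibration uses 20 seeds of 50,000 cases at
relative risk 1 throughout. Every stochastic choice is drawn from one
seeded generator in a fixed order, so bundles are byte-identical across
runs; the suite verifies this by hashing emitted files.

## Descriptives and numerical conventions

Characteristics tables use age bands `<18, 18–44, 45–64, ≥65, unknown`
(left-closed), report-count denominators, and top-5 truncation for
countries and routes. Onset time is event date minus the earliest
primary-suspect therapy start, in days; zero is legal, negative is
treated as missing. Quartiles use R's default linear interpolation
(`stats::quantile` type 7) — no quartile convention is authoritative for
this analysis style, and the tests pin the choice against an inline
sort-and-interpolate oracle. Statistics are reported at 2-decimal
rounding with full precision available via the pipeline's
`full_precision` flag; all internal computation is double precision.

## Problem sizes used by the test suite

The regression fixture runs in milliseconds. Property suites use 1,000
random tables. End-to-end recovery uses 20 seeds × 100,000 cases for
power and 20 seeds × 50,000 for null calibration (about a minute in
total); exact dedup/cohort recovery uses single bundles of 3,000–8,000
cases. These sizes are the package's own choice of a convincing yet
quick default; all scale linearly if larger checks are wanted.

## Known limitations

* No MGPS shrinkage or posterior-based EB05: small-`a` EBGM values are
  unshrunk O/E ratios.
* No multiple-testing control; signal lists are screening output, not
  confirmatory inference.
* The pregnancy-demographics exclusion rules are configurable policy,
  not a published algorithm; defaults are documented above.
* The ingestion layer targets the modern quarterly dialect; the legacy
  pre-2012 schema and XML ICSR are not supported.
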