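---
title: "Disproportionality signal detection for antiresorptive-related ONJ"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection for antiresorptive-related ONJ}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onjsignal)
```

## The problem

Osteonecrosis of the jaw (ONJ) is a rare, serious adverse reaction to
antiresorptive drugs -- bisphosphonates (zoledronic acid, alendronate,
pamidronate, risedronate, ibandronate, etidronate), the RANKL inhibitor
denosumab, and the sclerostin inhibitor romosozumab. Because ONJ is too
rare for randomised trials to characterise, its drug associations are
studied in spontaneous reporting systems such as FAERS: large, passively
collected databases of adverse-event reports. Spontaneous data are noisy
-- reports arrive in multiple versions, drug names are verbatim strings,
dates may carry only a year or a month -- so any analysis is as much a
curation problem as a statistical one.

`onjsignal` implements the complete analysis path: reading the
FAERS-style "$"-delimited quarterly tables, case deduplication, drug
normalisation, indication mapping, reporting-odds-ratio (ROR) signal
detection overall and within indication and dose strata, time-to-onset
summaries with Mann-Whitney comparisons, and descriptive breakdowns.
Because the full database is tens of millions of reports and cannot be
bundled, the package ships a synthetic spontaneous-report generator with
known ground truth, so every stage is exercised and calibrated at desk
scale.

## The disproportionality model

For one drug--event pair the deduplicated reports are cross-classified
into the 2x2 table

|                      | event of interest | other events |
|----------------------|-------------------|--------------|
| suspect drug (PS)    | a                 | c            |
| all other drugs      | b                 | d            |

where "suspect drug" means the ingredient appears on the report with the
primary-suspect (PS) role code. The reporting odds ratio is

$$\mathrm{ROR} = \frac{a\,d}{b\,c},\qquad
95\%\ \mathrm{CI} = \exp\!\left(\ln \mathrm{ROR} \pm
1.96\sqrt{\tfrac1a+\tfrac1b+\tfrac1c+\tfrac1d}\right),$$

the Woolf log-scale interval. A pair is flagged as a *signal* when
$a \ge 3$ and the lower confidence bound is strictly greater than 1
(one-sided on the lower bound, so under the null the criterion fires in
roughly 2.5% of tables with $a \ge 3$; the suite verifies the empirical
rate stays below 5%).

Numerical choices:

* **Zero cells** make the ROR incalculable; the result is flagged, and
  the Haldane--Anscombe correction (add 0.5 to every cell) is available
  only by explicit opt-in. Silent continuity correction changes small-count
  RORs materially and is never applied by default.
* **The interval radical.** Typeset renderings of the Woolf interval are
  ambiguous between $1/a$ and $1/(a{+}1)$ terms. The standard Woolf form
  is the default; the `plus_one` variant is available behind
  `compute_ror(ci_form = "plus_one")` for transparency.
* **$z = 1.96$** (95%) to match standard practice, parameterised for
  reuse.

## The event and case definitions

The ONJ event is defined by two MedDRA preferred terms --
"osteonecrosis of the jaw" (10064658) and "exposed bone in jaw"
(10071014). Matching is by PT code when the reaction row carries one,
else by case-insensitive name (FAERS REAC rows sometimes carry names
only). A case with both terms counts once.

Deduplication keeps, per case id, the highest case version, breaking
ties by latest report year and then largest primary id; the operation is
idempotent and its output size equals the number of distinct case ids.
"Primary suspect" is defined at report level: a case counts as exposed
when *any* of its drug rows carries the ingredient with role PS, and it
counts once even if data errors produce several PS rows.

## Stratified analyses

Two stratifications are supported, each with its own analysis universe:

* **Indication HLT.** Reports are stratified by the high-level term that
  the PS drug's indication resolves to; the universe of a stratum is the
  set of reports in that HLT. Reports whose indication resolves to no
  HLT are excluded from the stratified universe. Whether the comparator
  cells $b$ and $d$ should come from the stratum or from all reports is
  genuinely underdetermined in practice; the package defaults to the
  stratum-restricted universe and exposes `universe = "full"` as the
  alternative, asserting neither as canonical.
* **Dose-frequency-indication.** Reports with complete dose label,
  frequency and mapped indication category on the PS drug are stratified
  by (dose, frequency, category); records missing any component are
  excluded, mirroring complete-case matching. Categories are
  Osteoporosis, Malignancy, Metastasis, and Prophylaxis -- prophylaxis
  is kept as its own category rather than merged into osteoporosis,
  because prophylactic use is a distinct exposure context (and the
  published dose-stratified results report it separately).

Indication merging is configuration, not code
(`default_indication_rules()`): the term lists are exact-match and
user-extensible. The osteoporosis-related list contains both
"osteoporosis" and "osteopetrosis"; published merging lists name
osteopetrosis, which is plausibly a slip for osteoporosis, so both are
included and the choice is documented rather than silently corrected.
When a case carries different indications on different drug rows, the
group attached to the PS drug row is used.

## Time to onset

Onset is the calendar-day difference from therapy start to event date,
computed only when both dates have full day precision -- partial dates
are excluded, not imputed, because imputing the first of a month or year
would bias onsets downward; exclusion counts are reported. Negative
differences (event before therapy start) are data errors and are
excluded with a logged reason. When a case has several therapy start
dates for one ingredient, the earliest complete date is used.

Group summaries are median (Q1, Q3) with linear interpolation between
order statistics (`stats::quantile` type 7). Published onset quartiles
are fractional, which proves an interpolating convention was used; the
exact convention is unstated, so the most common one is chosen and
documented. Groups are compared with the two-sided Mann--Whitney test at
$\alpha = 0.05$: the U statistic from midrank rank sums, exact
permutation p when $n_1 n_2 \le 400$ with no ties, else the normal
approximation with tie and continuity correction (delegated to
`stats::wilcox.test`, which implements exactly this switch).

## Descriptive statistics

Categorical breakdowns report counts with percentages rounded half-up to
two decimals (base `round()` is round-half-even, which differs on
boundary values such as 0.125). Outcome codes may repeat per case, so
outcome percentages are shares of outcome occurrences and need not sum
to case totals. Yearly report counts are zero-filled over the observed
range. A packaged fixture of published per-drug descriptive counts
(`load_onj_descriptive_counts()`) lets the percentage computation be
checked against printed values exactly; two cells of the published table
are arithmetically inconsistent with their own printed counts (by 0.01
and 0.05 points), and the reference values used in the tests are the
counts' implied values.

## The synthetic-report generator

`simulation_config()` defines the generative model; its defaults in
`scenario_paperlike()` are chosen once to mirror the structure of the
real analysis at desk scale:

* One PS drug per report from a configurable mix: eight antiresorptive
  ingredients plus a comparator pool of unrelated drugs (so the $b$/$d$
  cells are populated the way a full database populates them).
* An indication drawn per drug (oncology-dominant mixes for zoledronic
  acid and pamidronate, osteoporosis-dominant for the oral
  bisphosphonates and romosozumab, mixed for denosumab), and a
  dose/frequency regimen per drug ("4 mg" Q4W and "5 mg" QY zoledronic
  acid, "120 mg" Q4W and "60 mg" Q6M denosumab, and so on).
* Events occur per report with a background probability, tilted on the
  logit scale by $\ln\theta$ when a signal row matches the drug (and
  optionally the indication group). The odds tilt makes the configured
  $\theta$ *exactly* the population odds ratio of the pair, which gives
  clean parameter-recovery semantics: the suite verifies that the
  pipeline's 95% CI covers $\theta \in \{1, 5, 10\}$ in 93--97% of 500
  replicates of 20,000 reports.
* Therapy start precedes the event date by a log-normal gap (strictly
  positive, right-skewed -- the shape of published onset quartiles),
  with per-(drug, indication-group) medians around 1.3--2 years for
  most drugs and around 5 months for romosozumab.
* Duplicate case versions (5%), partial dates (15%), missing dose or
  indication data (25%/10%), concomitant role-C drugs (30%) and a
  companion "exposed bone in jaw" PT on 10% of ONJ reports exercise the
  curation paths.

What the generator does **not** emulate: reporting dynamics over time
(Weber effect, notoriety bias), correlated polypharmacy,
manufacturer-specific duplicate patterns beyond simple versioning, or
free-text drug-name noise. Passing tests therefore demonstrate that the
statistical machinery is correct and calibrated under the stated model,
not that real FAERS extracts are free of biases that disproportionality
methods inherently carry.

## Problem sizes and runtime choices

The test suite runs the oracle-equivalence checks on 2,000-report
datasets (every contingency cell compared with an independent per-report
classification loop), the coverage experiment at 500 replicates of
20,000 reports per $\theta$, and the Mann--Whitney null calibration at
1,000 replicates; these sizes give binomial standard errors of about 1
percentage point on coverage estimates while keeping a full run in
minutes on one CPU.

## Known limitations

* ROR is a reporting association, not incidence or relative risk; the
  package deliberately implements no other disproportionality statistic.
* The bundled vocabulary is a fixture covering the terms this analysis
  needs, not a substitute for RxNorm/MedDRA services; unmapped drug
  names pass through tagged, and unmapped indications are excluded from
  stratified universes.
* One country field per report is exposed (the reporter country), the
  only geography reliably present in the quarterly tables.
* Onset analysis reports raw quantiles; there is no censoring model.
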