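---
title: "Bulk-tank SCC compliance: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bulk-tank SCC compliance: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bulkscc)
library(dplyr)
```

## The problem

Milk sold for manufacture in the EU must satisfy a bulk-tank somatic cell
count (SCC) criterion: a three-month rolling geometric mean no greater than
400,000 cells/mL, with a further three months of warnings allowed to correct
an exceedance before a herd becomes liable for suspension from supply. In
Ireland, SCC values from November to February are additionally multiplied by
seasonal adjustment factors below 1, originally motivated by the hypothesis
that low winter milk volumes mechanically concentrate SCC. `bulkscc`
implements this regulatory calculation chain as a reusable, tested pipeline:
cleaning of raw collection-day records, monthly and rolling geometric means
under the two calculation methods the legislation admits, the
warning/suspension state machine, and side-by-side comparison of compliance
outcomes with and without the seasonality adjustment. Because national
bulk-tank datasets are confidential, the package also ships a synthetic-data
generator that emulates their statistical structure and data-quality
defects, so every downstream stage is testable without access to real data.

All SCC values inside the package are on the x1000 cells/mL scale; the CSV
interchange format uses cells/mL, the unit the legislation is written in.

## Cleaning model

`clean_records()` applies three steps, in a fixed order so the reported
counts are deterministic:

1. SCC results recorded as 0 become missing — a zero bulk-tank SCC is a
   recording artefact, and treating it as data would drag geometric means
   toward zero (the geometric mean of any set containing 0 is 0);
2. records with negative volume are removed; zero volumes are retained,
   since only negative values are physically impossible;
3. multiple records per herd-day are merged: volumes are summed, and when
   several SCC results are present the merged SCC is the volume-weighted
   mean of the day's values, weighted by that day's collection volumes.

Two merge corner cases are underdetermined by the stated rules and are
pinned here (and covered by tests): an SCC value on a record without a
volume receives a weight equal to the mean of the day's known volumes
(equal weights if the day has no volumes at all), and a day with several
volumes but exactly one SCC keeps that SCC with the volumes summed.
Cleaning is idempotent and conserves total non-negative volume.

## Monthly and rolling geometric means

The monthly statistic is the geometric mean of a herd's SCC tests in a
calendar month, computed in the log domain (`exp(mean(log(x)))`). The
seasonal adjustment multiplies the monthly geometric mean by the factor of
that (year, month); months without a configured factor use 1. The shipped
`irish_seasonal_factors()` table carries the published 2013 and 2014 values
(2013: January 0.39, February 0.74, November 0.78, December 0.47).

Adjusted monthly means are categorised as low (< 200), mid (200–400) or
high (> 400, x1000 cells/mL). The boundary values 200 and 400 are assigned
to the middle category: the legislation's warning trigger is a strict
"exceeds 400,000 cells/mL", and the category bands are printed as
`<200,000`, `200,000–400,000`, `>400,000`. The boundaries have probability
zero under continuous data but must be pinned for reproducible tests.

Two calculation methods for the three-month rolling geometric mean both
conform with the primary legislation:

* **Method 1** — the geometric mean of the monthly geometric means of the
  current and two preceding months, each monthly mean seasonally adjusted
  first. All available SCC tests are used, whether or not a volume was
  recorded with them.
* **Method 2** — the geometric mean of **all individual** SCC tests in the
  three-month window, each test first multiplied by its month's factor. By
  default only records carrying both an SCC result and a volume are used;
  `include_scc_without_volume = TRUE` admits volume-less tests (the
  sensitivity this switch quantifies can be substantial at national scale).

The two methods coincide exactly when every month in the window contains
the same number of tests (the geometric mean of equal-sized geometric means
equals the pooled geometric mean); with unequal counts method 2 weights
months by their test counts, so a burst of low or high tests in one month
moves it further. Both implementations are checked against a brute-force
log-domain recomputation on randomized histories.

A rolling value exists for month *m* only if months *m*, *m*−1 and *m*−2
each contain at least one eligible test, where eligibility is evaluated on
the record set the method itself uses. A calendar month without eligible
tests is a break in supply and resets the window: the two following months
are incalculable. The start of the dataset is treated as an enforced break,
so no rolling value exists before the third month of data. Month arithmetic
uses calendar months throughout, not 30-day windows; there is no
partial-window fallback and no interpolation across gaps.

## The eligibility state machine

`assign_statuses()` maps a rolling series to monthly statuses with a
one-month lag: the status of month *m* is determined by the rolling mean of
month *m*−1. An incalculable or absent preceding value gives
`incalculable`; a value of at most 400 gives `compliant` (this also ends a
suspension); a strict exceedance raises the warning level one step above
the previous month's level, starting at `warning_1` from compliant or
incalculable and capping at `liable_for_suspension` after four consecutive
exceedances. Three consequences follow mechanically and are asserted as
properties: statuses escalate at most one step per month; the first warning
cannot occur before the fourth month after a break; and no herd can be
liable for suspension within six months of a break.

Two behaviours are not fully specified by the source rules and are design
choices here: an incalculable gap resets the warning ladder (warnings do
not survive a break in supply, consistent with the rolling mean itself
being reset), and a herd that recovers compliance after suspension
re-enters the normal ladder, so its next exceedance yields `warning_1`.
Because the monthly grid spans the dataset's calendar months, the first
assignable status in a single-year dataset falls in April (from March's
rolling mean), with January–March incalculable.

`max_noncompliance()` reduces a timeline to the most severe status ever
reached; herds with only compliant and/or incalculable months are
`always_compliant` (herds that never have a calculable month cannot be
classified otherwise with a fixed whole-population denominator).

## Scenario comparison

`run_scenario()` executes the full chain; with `use_adjustment = FALSE` the
factor table is replaced by all ones. Since every seasonal factor is at
most 1, removing the adjustment can never lower any rolling mean, hence
never lowers a month's category, a month's status or a herd's maximum
level. `cross_tabulate()` exploits this: the joint distribution of maximum
levels with vs without adjustment has a structurally zero lower triangle,
and the relative change in liable herds, (without − with) / with, is the
headline scenario statistic. Percentages are reported against the fixed
denominator of all herds in the dataset; the per-month supplier counts are
also emitted so either denominator can be used.

## What the synthetic generator emulates — and what it does not

`generator_config()` defaults describe a one-year national dataset:

* **Scale**: 16,740 herds collected every 3 days (override `n_herds` for
  desk-scale work; tests and examples here use 40–1,200 herds, which keeps
  any single run under a minute on one CPU).
* **SCC**: herd-level log-normal with `scc_log_mean = log(177)` and
  `scc_log_sd = 0.42`, test-day log-noise `scc_test_sd = 0.28`, a winter
  elevation `1 + 0.2 * cos(2 * pi * (month - 1) / 12)` peaking in January,
  and 4% chronically high herds inflated 2-fold. These were calibrated by
  pilot simulation so that the marginal SCC distribution reproduces the
  published national profile (5th/50th/95th percentiles near 70/192/427,
  mean near 214, x1000 cells/mL) within 10% across seeds.
* **Volume**: a log-normal herd daily-volume scale (median 2,680 L at curve
  weight 1, log-SD 0.7) modulated by a 12-month supply curve peaking in May
  and troughing in December–January, reproducing a usable-stratum monthly
  volume median near 22,000 L. No herd-size distribution is published, so
  this law is a free modelling choice exposed in the config.
* **Identifiers**: 60.4% of herds carry only a co-op code, stable within
  the year, mirroring the share of records lacking a national identifier.
* **Supply breaks**: 45% of herds have no January records, approximating
  the seasonal dry period; break months are configurable.
* **Defects**: zero-SCC results (rate 0.028), negative volumes (5e-5),
  duplicated herd-days (0.018; the day's volume is split and each half gets
  an independent SCC draw, exercising the weighted-mean merge), and SCC
  results without volume (0.0042). Defect classes are assigned exclusively
  per record so the realised injected counts — attached as an attribute and
  returned by `injected_defects()` — are exactly recoverable by the
  cleaning report.

The generator does **not** model cow-level infection dynamics, persistence
of elevated SCC across months beyond the herd-level mean, multi-year
supply, or herds supplying two co-ops at once. Consequently, passing tests
demonstrate that the calculation chain is correct and that the scenario
contrast behaves as the anti-dilution monotonicity argument requires; they
do not validate the national-scale counts (860/974 liable herds and
similar), which depend on the confidential source data and its particular
autocorrelation structure.

## Numerical choices

* All geometric means are computed in the log domain; full floating
  precision is kept internally and rounding to 2 decimals happens only at
  reporting. The worked-example tests accept ±0.03 on rolling values
  because the published table's rounding pipeline is unstated.
* Percentiles use `stats::quantile()` type 7 (the R default).
* Degenerate inputs fail loudly: empty record sets, non-positive SCC values
  in geometric means, unparseable dates and non-numeric fields are errors
  with classed conditions, never silent drops.
* Determinism: `generate_herd_records()` evaluates under
  `withr::with_seed(config$seed)`, so identical config and seed give
  byte-identical output.

## Problem sizes used in the shipped checks

Unit and property tests run on 10–300 herd populations; the oracle
comparison uses 1,000 randomized single-herd histories pooled into one
dataset; the distribution-calibration check generates about 140,000 records
from 1,200 herds. These sizes were chosen so the full suite completes in a
few minutes while keeping every Monte-Carlo margin comfortable.

## Known limitations

* Single-year analyses only; no cross-year record linkage, so the first
  three months of any dataset are a burn-in with incalculable status.
* The re-offence path after a suspension and the survival of warnings
  across breaks are design choices (documented above), not settled law.
* Volume-by-category summaries assign a herd's whole monthly volume to the
  herd's category for that month.
* The Kolmogorov–Smirnov usable-vs-unusable distribution comparison is out
  of scope; `describe_usability()` provides the descriptive strata only.
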