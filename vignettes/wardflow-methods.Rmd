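---
title: "Methods: interval census and staffing-mismatch analytics in wardflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interval census and staffing-mismatch analytics in wardflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wardflow)
```

## The analysis model

`wardflow` treats a hospital as a set of units on which two kinds of
half-open intervals live: patient **stays** (one contiguous presence of a
case on one unit, opened by an admission or transfer-in and closed by a
discharge or transfer-out) and nurse **shift segments** (one contiguous
working interval; breaks split a shift into two segments). All quantities
of interest are functionals of these interval sets evaluated on a fixed
lattice of slot instants:

* the **census** of patients and of nurses per qualification group at each
  slot instant;
* the **patient-to-nurse ratio** per group, with its median-based extreme
  thresholds;
* the census-normalised **turnover** (admissions, discharges, transfers
  in/out per slot divided by the patients present).

The default lattice has 48 slots of 30 minutes per calendar day. This
resolution is a compromise: fine enough that patients who stay for less
than one shift, or nurses working half or overlapping shifts, are resolved,
and coarse enough to keep three years of a 70-unit hospital tractable. The
package lets the increment vary (any divisor of 1440 minutes); on smooth
flows the mean occupancy computed at 20-, 40- and 60-minute lattices
differs from the 30-minute value by well under 1% (this is asserted in the
test suite).

### Sampling and binning conventions

Three conventions fix every boundary case; all are deliberate and are used
consistently across modules:

* **Point-in-time sampling.** A patient is counted at slot instant `t` iff
  `entry <= t < exit` (and analogously for nurse segments, so a nurse on
  break at `t` is not counted). Interval-averaged occupancy would be an
  alternative, but counts "at each data point" are the quantity the
  downstream ratio is defined on.
* **Half-open membership.** Because a transfer's exit and entry share one
  timestamp, half-open membership guarantees a transferred patient is
  counted in exactly one unit at every instant.
* **Event binning.** An event at time `tau` belongs to the slot whose
  window `[t, t + interval)` contains `tau`.

With these conventions the conservation identity
`census(t+1) - census(t) = entries(slot t) - exits(slot t)` holds exactly
*provided no event falls exactly on a slot boundary*. Event times in the
synthetic generator are therefore continuous (sub-second), and the sheet
writers keep millisecond precision, which makes boundary ties a
measure-zero event rather than a systematic one. Real exports with
minute-resolution timestamps are still accepted; the conventions above then
decide boundary ties deterministically.

Calendar time is naive wall-clock time: every day has exactly 1440 minutes
and 48 slots, and no daylight-saving arithmetic is applied. Working-hours
segments whose end time is not after their start time are interpreted as
crossing midnight into the next day.

## Linkage and the exclusion funnel

The two sources are merged on six keys (case, nurse, contract, unit, date,
time). The stages, each recorded in the funnel with numerator, denominator
and a percentage rounded **half-up to one decimal**:

1. restrict activity rows to inpatient units and direct/indirect care
   (dropping administrative, teaching, continuous-education and absence
   rows), after full-row deduplication;
2. nurse side: join qualification group and working hours on
   (nurse, contract, date). Core nurses (RN/LPN/other) with care activity
   but no working-time rows on a date are excluded *for that date only* and
   counted as excluded person-days; students and externals, who have no
   working-time breakdown at all, are routed to a daily-presence table.
   Contract identifiers are dropped after the join;
3. patient side: movement events are ordered and paired into stays
   (admission/transfer opens, transfer/discharge closes; unpairable
   sequences are rejected with a reason, never silently dropped), cases
   flagged outpatient are excluded, as are healthy newborns in the
   Maternity & Gynecology department (a flag in the discharge sheet;
   DRG/ICD-based newborn detection is out of scope);
4. deidentification to `Patient1…`, `Nurse1…`, `Unit1…`, assigned in sorted
   order of the raw identifiers so repeated runs agree; the map is
   discarded unless explicitly kept.

A case is an admission episode, not a person: readmissions are distinct
cases. Each unit's department is inferred as the modal department of the
cases staying on it, which is exact whenever units do not change
departments mid-study.

## Ratios, extreme mismatch, turnover

The ratio at a data point is `patients / nurses` of one group. Where the
group's nurse count is zero the ratio is **missing** — not zero, not
infinite — and missing points are excluded from medians and from the
percentage denominators; a `n_zero_nurse` column preserves how often this
happened. The extreme thresholds per stratum are

```
ELT = median - median/2 = median/2        EHT = median + median/2 = 1.5 * median
```

so `EHT = 3 * ELT` for every non-degenerate stratum, and the three
percentages (strictly below ELT, strictly above EHT, inside the closed
band) partition 100%. Strict inequalities were chosen because a value *at*
a threshold is not "far beyond" it; with the 50% band this only matters for
ties. The stratum for the median is the unit × nurse group over the **full
study period** (not per timepoint): the thresholds are meant as a
fixed yardstick against which individual data points are classified.
Strata with median 0 (typical for LPNs and others at night) are reported
but flagged `degenerate`, because both thresholds collapse to zero and the
percentages lose meaning. Quantiles use the linear-interpolation convention
(`stats::quantile` type 7) throughout.

Key-timepoint summaries (02:00, 10:00, 18:00; weekend = Saturday/Sunday)
pool the unit-level data points of a department. Department mean profiles
first average within unit (per weekday × slot), then across units, with a
t-based confidence interval on the unit means — with typically 3–12 units
per department a normal-quantile interval would be anticonservative.

Turnover ratios divide the four event counts by the census **at the slot
instant** (sampling at slot start). Whether patients arriving within the
same 30-minute window should count in the denominator is genuinely
ambiguous; sampling at slot start was chosen for consistency with the
census module and is the convention the conservation identity assumes.
Zero-census slots yield missing ratios with counts preserved; ratios may
exceed 1 and are not capped. Department profiles sign exits negative, for
diverging bar charts, while counts remain unsigned.

The descriptive overview computes LOS as the whole-day calendar difference
(discharge date minus admission date, times ignored) and "patients/day/unit"
as the census at a fixed daily reference slot, 12:00 by default and
configurable — a midnight census or a daily distinct-patient count would be
defensible alternatives, so the choice is a documented parameter rather
than an assertion.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes, not
any particular hospital:

* **Admissions**: a time-inhomogeneous Poisson process on an hour-of-day ×
  weekday intensity grid. The default profile peaks at 08:00–10:00
  (0.6/h/unit), runs at 0.25/h/unit during the day, 0.05/h/unit overnight,
  with weekends scaled by 0.6 — the canonical diurnal ward pattern.
* **Length of stay**: lognormal by default (`meanlog = log 3`,
  `sdlog = 0.7`, i.e. median 3 days and a right skew), configurable per
  department as lognormal, gamma or exponential. Right-skewed LOS is the
  empirical norm; the exponential option exists mainly because it makes
  Little's-law validation exact.
* **Transfers**: Poisson with 0.05 expected transfers per patient-day,
  destination uniform over the other units; a transfer is instantaneous.
* **Roster**: a three-shift template (night 23:00–07:15, morning
  07:00–15:30, evening 15:00–23:15, with 30-minute breaks inside fixed
  windows and reduced weekend levels). Each unit draws from a persistent
  nurse pool about twice the maximum simultaneous demand, so the same
  nurses reappear across days; every nurse holds one contract. Students
  and externals are present with Poisson daily intensity derived from the
  group-mix proportions and appear only as daily presence.
* **Defects**: a configurable fraction of core nurses lose all
  working-hours rows; a fraction of cases is flagged outpatient (present in
  movement and activity data, absent from discharge data); a fraction of
  maternity cases are healthy newborns (age 0, newborn flag). Optional
  outpatient units contribute activity-only rows that the inpatient filter
  must remove.
* **Truth**: the generating stays, segments and flagged cases are returned
  alongside the sheets, so linkage and census can be validated exactly:
  with all defect rates at zero the recovered stays and segments equal the
  truth to the millisecond precision of the sheets.

What the generator does **not** emulate: clinical pathways and acuity,
bed-capacity constraints, seasonal trends, multi-contract nurses, nurses
working two units on one day, and correlated admission/discharge scheduling
(e.g. discharge rounds). Passing tests therefore demonstrate the pipeline's
correctness on data with the declared structure, not that real hospital
data meet that structure.

All generator operations are deterministic given the configuration seed
(each stage draws from its own derived seed, so partial reruns agree with
full ones).

## Validation strategy and problem sizes

The test suite validates every counting path against independent
brute-force oracles (per-slot scans over 1,000 random stays and 200
segments), checks the conservation identity between census first
differences and turnover event counts with zero tolerated violations,
recovers the theoretical occupancy `lambda * E[LOS] = 36` of a constant-rate
ward (0.5 admissions/h, exponential LOS of mean 3 days, 365-day horizon,
30-day warm-up) within three batch-means standard errors, and exercises the
linkage funnel on published worked examples. Simulation sizes in the suite
— typically 2–6 units over 2–16 weeks, and one single-unit year for the
queueing check — were chosen as the smallest scales at which the stochastic
assertions have comfortable power; all complete in well under a minute
each.

## Known limitations

* The funnel reproduces published percentages under half-up rounding; a
  source that truncated a percentage will disagree in the last decimal.
* Unit-to-department inference is modal and can mislabel a unit if most of
  its stays come from transferred-in cases of other departments.
* Degenerate strata are flagged rather than suppressed; consumers must
  filter on the flag before interpreting extreme percentages.
* The pipeline is descriptive by design: no inferential statistics beyond
  the t-intervals on department means are provided, and the extreme
  cut-offs at ±50% of the median are illustrative conventions, not
  clinically validated thresholds.
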