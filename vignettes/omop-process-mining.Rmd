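---
title: "Mining healthcare processes from the OMOP CDM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining healthcare processes from the OMOP CDM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omopflow)
```

## Why event logs from a CDM

Process mining derives process models from event logs: sets of cases, each a
time-ordered sequence of events with an activity, a timestamp and an
originator. Hospital event logs have traditionally been cut from
heterogeneous EHR extracts, which makes studies hard to reproduce across
sites. The OMOP Common Data Model standardizes both the relational schema and
the concept vocabulary, so a log specification written once runs against any
OMOP site. `omopflow` implements that specification layer in R: a minimal CDM
data model with validation, four process-type extractors, the
matching-rate clinical-pathway (CP) miner, and the discovery analytics
usually applied to the resulting logs.

A log specification (`log_spec()`) has five elements:

- **process type** — which visits form cases: inpatient (visit concept 9201),
  outpatient (9202), ER (9203), or the patient journey (cases are persons).
  Concept 262 codes visits that are both ER and inpatient; it is included in
  inpatient and ER extraction by default (`include_262 = FALSE` to disable),
  since sites use it for either role.
- **period** — a half-open `[start, end)` window; a visit belongs to the
  period by its `visit_start_datetime`. Half-open windows make adjacent
  periods partition cleanly.
- **scope** — which of the activity-bearing tables contribute events
  (condition_occurrence, procedure_occurrence, measurement, drug_exposure,
  device_exposure, observation, cost, note). Cost and note carry simplified
  `(concept_id, datetime)` columns here; the full CDM cost table has no
  event datetime of its own, but payments and notes are useful activities,
  so the package treats them like the five clinical event tables and
  documents the deviation rather than dropping them.
- **field** — fixed: case id, event id, activity, timestamp, originator.
- **feature** — optional enrichments, currently the department attribute
  (resolved provider → care site). Whether a department should come from
  provider specialty or care site is site-specific; the care-site name is the
  default because it exists in the minimal schema.

## Extraction rules worth knowing

**Activities.** Inpatient activities are concept renderings
`"<id> (<name>)"` — numerical codes stay visible because they are the
portable identifiers. Outpatient and ER activities are table-level labels
(condition → Consultation, measurement → Physical examination & Lab test,
drug → Drug, procedure → Surgery & Radiology test, cost → Payment,
observation → Survey): administrative events such as registration or
scheduling are simply not recorded in most CDMs, so table names are the
honest granularity.

**ER boundaries.** Each ER case is framed by its admission source at visit
start (e.g. `8536 (Visit from home)`) and its discharge destination at visit
end, rendered `"<id> (Discharge to <dest>)"` where `<dest>` strips a leading
"Visit from"/"Transfer from" from the concept name. This gives
`8536 (Discharge to home)` for the home concept while transfer concepts keep
their full names. Stay length in hours (exact duration / 3600, two decimals)
is a case attribute; inpatient stays use calendar-day differences, so an
admission on Aug 1 discharged Aug 4 is 3 days regardless of clock times.

**Patient journeys.** Case id is the person; qualifying patients have a
cohort visit starting in the period, and all their visits in the (wider)
`journey_window` are kept. At visit level each visit is one event labelled by
type; at descendant level within-visit events are labelled
`<Type>_<k>_<Table>` with `k` the per-type chronological index
(`Out_1_Drug`, `In_1_Procedure`, ...), duplicate (label, calendar date)
events collapse to the first occurrence, and optional `_Start`/`_End` markers
frame each visit. An inpatient hospitalization is always a single visit
(`In_1`), however long.

**Equal timestamps** are ordered by source-table rank (condition < procedure
< measurement < drug < device < observation < cost < note), then row id. Any
fixed rank yields reproducible traces; this one follows the usual clinical
ordering of a day (diagnosis, intervention, monitoring, medication,
paperwork).

**Date-only timestamps.** Billing-adjacent tables often record only a
calendar date. The flag is inferred from the source text (a bare date), never
from a midnight clock value, because midnight can be a real time.
`repair_dateonly_timestamps()` re-sequences such events after the day's last
timed event (09:00 if none) in the priority order condition > drug > cost,
with the k-th successive gap `min + (max-min)(k-1)/max(1, K-1)` minutes over
the default range [5, 30]. A deterministic linear spread was chosen over
random draws so that repeated extractions are byte-identical; only the
plausible range of the gaps, not their exact law, is knowable anyway.

## The matching-rate CP miner

Case profiles anchor on the operation: the earliest event with the anchor
concept in each case defines day 0; the anchor event itself is excluded and
entries outside the `day_window` (default [-1, 2]) are dropped. Profiles hold
*distinct* `(relative day, concept, table)` entries — repeated
administrations of the same drug on the same day would otherwise inflate the
matched ratio; multiplicities are kept in a count column for reporting only.

For a pathway CP over profiles S₁, …, S_N the package computes

- application rate: the mean over pathway entries of per-entry case coverage,
- matched ratio: the mean over cases of |Sᵢ ∩ CP| / |Sᵢ|,
- matching rate: their sum.

The per-entry mean (rather than a per-case intersection share) is the form
consistent with a single top order showing near-total coverage while a
many-order pathway averages far less. Matching is day-aware by default — an
order matches only on its pathway day, which is what a day-structured CP
report means — with `day_aware = FALSE` available for sensitivity analysis.

Greedy selection appends the remaining candidate with the highest application
rate (`selection = "matching_gain"` instead scores the immediate
matching-rate gain; both are exposed because the matched ratio is additive
over distinct entries, making the gain cheap to compute). Ties break by
concept id then relative day, for determinism. The full metric curve is
computed to `k_max` (all candidates, capped at 500) and the optimal size is
the smallest k attaining the maximal matching rate. `exhaustive_cp_search()`
enumerates all size-k subsets (capped at 10⁶ combinations) as an oracle; the
greedy prefix can never beat it, and equals it on instances whose strong
entries dominate by a wide rate margin with uniform profile sizes. No
minimum-support pre-filter is applied to candidates: rare orders merely rank
low and cost nothing.

One known caveat: with these definitions a one-entry pathway of coverage
near 1 scores a matching rate near `1 + MR({e})`, which is already above
intermediate published checkpoints of some CP-mining write-ups; the additive
identity `AR + MR`, which the final metric triple of such reports does
satisfy, is what the package fixes and tests.

## Discovery analytics

`discover_dfg()` counts directly-follows pairs within each case's trace and
annotates edges with mean and median inter-event durations in seconds
(median is the robust choice for skewed clinical waits; both are exported).
Flow conservation — start(a) + inflow(a) = freq(a) = end(a) + outflow(a) —
is an invariant and is tested on every discovered graph. Self-loops are
retained: repeated same-day orders are real behaviour, not noise.

`filter_mainstream()` keeps the most frequent activities until their
cumulative share of events reaches `activity_fraction` (ties kept together),
rebuilds traces on surviving events, then prunes edges below the
`1 - path_fraction` frequency quantile without ever removing nodes. The
cumulative-coverage rule is an explicit stand-in for the proprietary
"mainstream behaviour" filters of commercial miners — fractions of 1 are
identities, which is the property downstream code may rely on.

`compute_variants()` ranks exact activity sequences; `dotted_chart()` emits
one point per event with cases ordered by start time or descending duration
and absolute or case-relative time; `los_summary()` reports n, mean, sd
(n−1 denominator; a single case reports sd 0 with a degenerate flag) and
median of the LOS case attribute.

## What the synthetic generator does and does not emulate

The generator exists to give every downstream stage a testable ground truth,
not to imitate medicine. Its defaults define the study conditions used
throughout the tests:

- **Inpatient** (`generate_inpatient_cohort()`): 300 patients, one inpatient
  visit each, stay length 4–8 days (probabilities .15/.30/.25/.20/.10),
  exactly one surgery event per case at least one day after admission, a
  planted pathway of 20 day-specific orders on days −1..+2 applied with
  probability 0.85–1.0, and 200 day-independent Bernoulli noise orders at
  0.01–0.15 per stay day. The anchor day is placed so every planted relative
  day fits inside the stay; otherwise empirical application rates would be
  biased below their nominal probabilities and recovery tests would measure
  the generator, not the miner. Event times are uniform over working hours
  (08:00–18:00) so dotted charts look plausible.
- **Outpatient** (`generate_outpatient_visits()`): per-patient visit counts
  1 + Poisson(2), per-visit event counts Poisson with per-table means over
  the six outpatient tables, and a configurable fraction (default 0.3) of
  condition/drug/cost rows degraded to date-only timestamps.
- **ER** (`generate_er_visits()`): admission-source and discharge
  distributions over the standard concepts {8536, 44790567, 8716, 8717,
  8756}, stay hours gamma-matched to mean 5.94 and sd 7.6 (floored at 12
  minutes), events from measurement/drug/observation/note.
- **Journeys** (`generate_patient_journeys()`): visit-type sequences drawn
  from a Markov chain over Outpatient/Inpatient/ER/Checkup/End (cap 20
  visits), materialized with strictly increasing non-overlapping windows and
  a small per-type event mix. The checkup visit concept (9205) is a synthetic
  stand-in — OMOP has no canonical checkup visit concept and study sites use
  local codes — and is configurable in the journey label map.

Randomness is organized as one sub-stream per patient index derived from the
config seed, so patient i's data do not change when `n_patients` grows; this
is also what the determinism tests pin down. What the generator deliberately
does **not** model: clinically plausible order co-occurrence, billing
semantics of the cost table, seasonal or weekday effects, inter-site
heterogeneity, and administrative activities absent from CDMs. Passing
recovery tests therefore show that the miner recovers a planted signal under
honest noise — not that it reproduces any particular hospital's pathway.

## Numerical and format choices

Timestamps are timezone-naive UTC at second resolution (published example
logs print minutes; seconds avoid artificial ties). CSV files are RFC-4180
with exact CDM column names; unknown extra columns pass through untouched.
XES export uses the standard `concept:name` / `time:timestamp` /
`org:resource` keys. Both CDM write/load and log CSV/XES round trips are
identities up to attribute ordering, and the tests assert it field by field.
Where a site populates `_date` rather than `_datetime` columns, the bare-date
text parses to midnight with the date-only flag set, which feeds the repair
step rather than erroring.

Test problem sizes are chosen to exercise the statistics at desk scale: 300
cases for pathway recovery (precision/recall ≥ 0.9 against the planted set,
empirical rates within 3 binomial standard errors), 2,000 cases for the
binomial sampling check, 1,000 patients for the Markov-chain frequency check,
1,000 random instances for the additive-identity property, and 50 instances
of ≤ 12 candidates for the greedy-vs-exhaustive oracle.

## Limitations

The package extracts what a CDM records. Administrative and operational
events (registration, scheduling, certificate issuance), nursing
interventions and diet information are not in scope because they are not in
the data; conformance checking against knowledge-based reference pathways,
Petri-net/BPMN synthesis, and organizational mining are out of scope by
design. The mainstream filter approximates, but does not claim to equal,
commercial tool semantics. Graph exports (DOT/JSON) carry no layout;
rendering is a consumer concern.
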