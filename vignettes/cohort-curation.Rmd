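---
title: "Curating infection and vaccination cohorts as person-day chronograms"
author: "cohortgram"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating infection and vaccination cohorts as person-day chronograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortgram)
```

## The data model

Observational cohort studies that follow vaccine and infection responses
scatter their information across sources with different shapes: a
per-participant metadata table (group labels, dose dates, usually a REDCap
export) and several sparse experiment tables keyed by participant and
calendar date (antibody titers from a LIMS, PCR and antigen results,
symptom diaries, viral sequencing calls).  Most analysis mistakes in this
setting are date-arithmetic mistakes: joining an assay to the wrong visit,
counting an exposure on the wrong side of a dose date, or losing rows in
an ad hoc merge.

The chronogram model removes the joins from the analyst's hands.  A
`Chronogram` is a dense long-format table with **exactly one row per
participant per calendar day** over an inclusive study span
`[start, end]`.  Its invariants are:

* one row per `{participant, date}` key — never more, never fewer;
* every participant carries one row for every day of the span, so
  `rows = participants × days` (sub-cohort views relax this, and only
  this);
* dates are timezone-free whole calendar days (the unit of observation is
  the date; nothing in the model is finer-grained);
* each registered metadata column takes exactly one non-missing value per
  participant.

Columns carry roles: *metadata* (constant per participant), *experiment*
(sparse observations), and *annotation* (derived by this package).  The
key-column names and role registries travel with the object as slots, so
downstream functions need no re-declaration; `cgValidate()` audits the
invariants and returns a violation report rather than stopping at the
first problem.

Participant identifiers are opaque strings throughout and are never
coerced to numbers: clinical-database exports routinely carry identifiers
with leading zeros, and a silent `007 → 7` coercion breaks every
downstream join.

### Assembly

`cgAssemble(start, end, metadata, experiments)` generates the grid,
broadcasts the metadata, and places each experiment table's result
columns on their observation dates.  All input checking happens here, and
it is deliberately loud: duplicate `{participant, date}` keys in an
experiment, duplicate participant identifiers, experiment rows for
unknown participants, and observations dated outside the span all refuse
assembly with the offending table and key named.  In a curation tool,
silent data loss is strictly worse than a failed run; the one concession
is `dropOutOfSpan = TRUE`, which drops out-of-span observations *with a
logged count*.  Participants present in experiments but absent from the
metadata are refused rather than invented: the metadata table is the
enrolment roster.

Experiment tables may share participants and dates but not result-column
names — one table per assay modality, mirroring LIMS exports, with
provenance preserved by column naming.  `cgAddExperiment()` is guaranteed
to commute with assembly: adding a modality later gives cell-for-cell the
same chronogram as assembling with it upfront, so slow research assays
can be appended as they arrive.

Dates are parsed strictly (ISO-8601 by default; other dialects only via
an explicit `dateFormat`).  An ambiguous cell such as `"07/03/2021"` is a
per-cell error listing the offending rows — day/month order is never
guessed.  Missing values are canonicalized: `""`, `"NA"` and SQL `NULL`
all become `NA`, so one absent marker exists regardless of source
encoding.  The full uniform grid is generated even for dates before a
participant's enrolment; masking pre-enrolment days is an analysis
decision and is left to `cgFilter()`.

## Annotation

Annotations build on one another and their order matters; each function
checks its prerequisites and says which step to run first.

### Infection episodes

Evidence for one infection is typically scattered over a few days —
symptoms on Monday, a positive PCR on Wednesday, sequencing on Friday.
`episodesFind()` scans user-chosen columns for user-chosen values
(exact equality after trimming and case-folding by default; regular
expressions behind a flag, since exact matching fails loudly while a
mistyped regex fails silently) and merges, per participant, evidence days
into maximal clusters in which consecutive evidence days lie at most
`maxGap` days apart.  Each cluster is one episode spanning first to last
evidence day, numbered chronologically from 1.

Two reading choices deserve note.  First, days *between* two evidence
days of one episode belong to the episode even if they carry negative
tests — we take the maximal-cluster reading; the alternative (splitting
on intervening negatives) would make episode boundaries depend on
testing frequency.  Second, the episode ends on its last evidence day; no
fixed episode length is imposed, and analyses that want "+N days after
onset" express that with `windowByEpisode()`.

The default `maxGap = 7` days reflects the few-days scale on which
confirmatory evidence accumulates; it is a parameter, not a claim —
pathogen-specific conventions (e.g. a 90-day SARS-CoV-2 reinfection
definition) are expressed by changing it.

### Seroconversion windows

A serological marker that flips from negative to positive between blood
draws implies an exposure inside the inter-draw window.  For
anti-nucleocapsid IgG under spike-only vaccination this specifically
implies *infection*, since nucleocapsid is encountered only in intact
virus.  Because venepunctures are weeks to months apart, these windows
are far wider than test-evidenced episodes, so
`episodesFindSeroconversion()` keeps its output separate
(`sero_*` columns and `seroconversionTable()`).

The window is half-open, `(last_negative, first_positive]`, so one
measurement date can never sit in two windows.  Missing marker values
are skipped, not treated as negative.  Participants positive at their
first measurement are flagged `sero_baseline_positive`, not counted as
converters; positive→negative reversions are flagged but create no
interval; repeated conversions are all reported.

### Counting and attribution

`vaccinesCount()`, `episodesCount()` and `exposuresCount()` add
per-row cumulative counts.  Conventions, fixed and documented because
one-day shifts move analysis windows:

* counts step up **on** the event date (day 0 of a dose is post-dose);
* an infection's event date is its episode start — the first day
  infection is evidenced; a seroconversion-only infection is dated at
  its first positive measurement (the conservative choice);
* `exposures_count = vaccines_count + episodes_count` row-wise, always.

Seroconversions detected serologically and episodes detected by testing
can be the same infection.  `episodesCount()` therefore counts a
seroconversion interval only when it is *sero-only*: no test-evidenced
episode starts inside the interval, nor within `seroLagDays`
(default 21) before its last-negative draw.  The lag term exists because
a blood draw taken a few days after infection onset can still read
negative; without it, an episode beginning just before a negative draw
would be double counted.  Twenty-one days is an upper-range IgG
seroconversion time; the switch and the lag are both arguments.  (The
include/exclude switch lives on `episodesCount()` rather than
`exposuresCount()` precisely so the row-wise sum identity above can
never be broken by mixing switch settings.)

### Antigenic histories

`antigenicHistory()` encodes each person-day's accumulated exposures as
an ordered string — `"V1:I1[Delta]:V2"` — with `V`*k* for dose *k*,
`I`*k* for the *k*-th infection, and a bracketed label when a filled
column (typically a sequencing call broadcast over its episode by
`episodesFill()`) provides one.  A same-day vaccine and infection are
ordered vaccine-first and flagged; some order had to be fixed, ties are
rare, and the flag makes them auditable.  The format is this package's
own convention, chosen to be compact, greppable, and round-trip
parseable (`parseAntigenicHistory()`).  Two invariants hold by
construction: the history at any date is a prefix of the history at
every later date, and its code count equals `exposures_count` on every
row.

## Sub-cohorting: filter, window, select

Hypothesis testing starts by extracting an analysis-ready sub-cohort in
three stages, each returning a *view* (key-unique, grid-incomplete,
provenance-stamped):

1. **filter** to relevant individuals — any row predicate over columns
   (`cgFilter(cg, exposures_count == 4 & episodes_count == 0)`);
2. **window** to dates around a per-participant reference event —
   a metadata date (`windowByMetadata`), an episode onset
   (`windowByEpisode`), or the *k*-th visit (`windowByVisit`).  Windows
   are inclusive at both ends, matching the way analysis windows are
   phrased ("28–35 days after the second dose" means both boundary days
   count), and offsets are signed so "before" needs no separate verb;
3. **select** exactly one row per participant (`selectVisit`), dropping
   rows missing the value column and keeping the earliest by default —
   a deterministic tie-break; `"last"` and `"nearest"` (to a reference
   date, ties to the earlier row) are available.

Participants that cannot satisfy a window (missing reference date,
absent episode, too few visits) are dropped with a logged count rather
than erroring: narrowing is the point of sub-cohorting, but it should
never be invisible.  Each stage appends a human-readable note to
`provenance()`, which is also serialized, so a saved sub-cohort carries
its own audit trail.

For post-second-dose peak comparisons, both a tight `[28, 35]` and a
permissive `[21, 35]` day window are defensible conventions; the
package's examples and acceptance checks use `[28, 35]`, and either is a
one-argument change.

## Serialization

`cgSave()` writes a directory: a JSON manifest (format tag
`cohortgram-v1`, key names, span, registries, provenance, per-column
storage classes, per-part MD5 checksums), the metadata collapsed to one
row per participant, the sparse observations (only person-days with at
least one non-missing experiment/annotation value), and the episode
tables.  Size therefore scales with observations, not with
`participants × days`; `cgLoad()` regenerates the grid.  Design choices:

* plain-text CSV/JSON parts keep the container inspectable and
  diff-able under version control;
* writing is deterministic (stable row and column order, fixed number
  formatting), so identical chronograms produce identical bytes;
* doubles are written with 17 significant digits, which round-trips
  IEEE values exactly; dates are ISO-8601;
* missing cells are written as the bare token `NA` — canonicalization
  guarantees no chronogram cell ever holds that literal string — so the
  empty string (a legitimate value: a pre-exposure antigenic history)
  stays distinct from missing;
* annotation columns are saved as data and **not** recomputed on load:
  a later algorithm change must never silently alter previously saved
  results.  Re-annotation is an explicit re-run of the pipeline;
* sub-cohort views save every retained row (their grid is not
  reconstructible from the span) plus the view flag and provenance.

On load the format version and every checksum are verified, and
observations falling outside the manifest's grid raise an integrity
error, which also catches a tampered span.

## The synthetic cohort generator

`generateCohort(cohortDesign(), seed)` emits the input tables of a
two-dose-interval vaccine study with known ground truth, so every
function above is testable end to end with no external data.  It
emulates the structure of a healthcare-worker cohort in which dose
spacing changed mid-campaign: participants split into long (10–12 week)
versus short (3–4 week) dose-interval groups, with and without prior
infection; anti-Spike titers with a post-dose-2 peak; anti-nucleocapsid
status including mid-study seroconverters; and scattered swab/symptom
evidence that episode merging must aggregate.

Default design values, chosen once as plausible for that setting:

| parameter | default | note |
|---|---|---|
| participants | 200 | hundreds-scale cohort, desk-testable |
| group fractions | 0.35/0.15 per interval group (uninfected/prior) | prior infection the minority |
| dose-1 months | Dec 2020 – Feb 2021 | campaign window |
| dose intervals | long 70–84 d, short 21–28 d | the defining grouping |
| visits | dose1 − (3–10) d; dose2 + 28–35 d; dose2 + 56–63 d | baseline, peak, decay |
| baseline titer GM | 5 (uninfected), 50 (prior) | arbitrary BAU-like units |
| peak titer GM | long\_N 2000, short\_N 1000; prior 5000/5000 | 2-fold effect only where uninfected |
| titer noise | log-normal, sdlog 0.5 | typical inter-individual assay spread |
| mid-study infection rate | 0.15, of whom 20% reinfected ≥ 60 d later | forces episode splitting |
| seroconversion lag | 14 d | inside the 21 d attribution default |

First-dose dates are produced the way a privacy-preserving public
release would be undone: the month is kept, the day-of-month is drawn
uniformly from 1..28 (never 29–31, so every month is valid), and all
downstream dates are recomputed from stored day-intervals
(`perturbDates()`), which preserves the intervals exactly.

The titer model is a log-normal around group geometric means.  That is a
deliberate simplification: the generator's job is to embed a known,
monotone group effect the pipeline must recover, not to model antibody
kinetics.  Its parameters are configuration, not biological claims.
Passing tests on this cohort therefore demonstrate correctness of the
*data mechanics* — grids, joins, merging, counting, windows,
serialization — and recovery of an effect of the embedded size
(2-fold in geometric mean against 0.5 sdlog noise, n ≈ 35 per group at
the peak visit).  They do not validate assay behaviour, real-world
seroconversion kinetics, missingness patterns of clinical data, or any
immunological conclusion.

The embedded-null check matters as much as the embedded effect: in the
prior-infected stratum the generator sets equal peak means, and the
recovery check asserts the long/short ordering is *not* systematically
won there (win counts within ±4 binomial SDs of 50/100 seeds).  A
pipeline that "finds" the effect in the null stratum would be
manufacturing it.

## Problem sizes and numerical choices

The bundled checks run at sizes chosen to exercise every code path at
desk scale: randomized grids up to 50 participants × 400 days; 1000
random evidence configurations (gap thresholds 0–30 days, evidence
densities up to 50%) against an independently coded graph-component
oracle; 1000 random marker sequences against a consecutive-pair scan
oracle; 100 generated cohorts for the counting/history invariants;
and 100 generator seeds for effect recovery on the default n = 200
design.  Episode merging is exact integer day arithmetic; there are no
tolerances anywhere in the core — the only floating-point surface is
titer values, which serialization preserves bit-exactly.

## Known limitations

* No REDCap/LIMS connectivity: the package starts from exported
  rectangular tables (CSV or SQL).
* One row per calendar day means sub-daily structure (two swabs in one
  day in one table) must be resolved upstream — by design, since the
  key uniqueness check is the contract.
* Sero-to-episode attribution is heuristic (the `seroLagDays` rule);
  studies with very frequent serology and overlapping infections may
  need to adjudicate manually from `seroconversionTable()`.
* The generator emits a regular three-visit schedule and
  monotone-by-construction titers; it does not simulate dropout,
  batch effects, or epidemic dynamics.
* Memory is O(participants × days × columns); at 10⁴ participants over
  two years (~7M rows) base-R data frames remain workable but chunked
  processing is the user's responsibility.
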