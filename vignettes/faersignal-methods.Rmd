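---
title: "Methods: disproportionality analysis of FAERS reports with faersignal"
author: "faersignal authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality analysis of FAERS reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem and the data model

Spontaneous adverse-event reporting systems such as FAERS collect safety
reports without a denominator: there is no count of patients exposed, so
incidence cannot be estimated. What can be estimated is
*disproportionality* — whether an event of interest is reported more
often, relative to all other events, for one drug than for a comparator
background. `faersignal` implements that analysis for the FAERS
quarterly ASCII distribution, with coagulation dysfunction under the
antibiotic tigecycline as the shipped, fully worked use case.

FAERS distributes five `'$'`-delimited tables per quarter (DEMO, DRUG,
REAC, THER, OUTC). Each *report version* carries a `primaryid`; each
*case* carries a `caseid` that may own several versions as a report is
revised. `FaersTables` holds the raw tables verbatim (all text, no type
coercion); `assembleReports()` joins them into case-report objects,
decoding outcome codes, reporter occupations and ages (units `DEC`, `YR`,
`MON`, `WK`, `DY`, `HR` are converted to years; values outside 0–150
years are treated as data errors and dropped with a warning). Only the
modern `primaryid`/`caseid` dialect is supported; the legacy ISR-keyed
dialect used before 2012Q4 has a different key structure, and one
consistent data model keeps every downstream contract testable.

Three policies are worth stating explicitly:

* **Deduplication.** Analyses count cases, not versions. For each
  `caseid` the version with the greatest FDA receipt date survives;
  receipt-date ties go to the greatest `primaryid` (digit strings
  compare by length, then lexicographically, which is numeric order).
  The rule is deterministic and idempotent.
* **Partial dates.** FAERS dates come as `YYYYMMDD`, `YYYYMM` or
  `YYYY`. Each date keeps an explicit precision flag and only
  day-precision dates participate in day arithmetic. Imputing a day
  inside a partial date would bias onset estimates in an uncheckable
  way, so it is never done; affected records are excluded and tallied.
* **Dirty codes.** Unknown outcome, age-unit, occupation or role codes
  are logged and skipped, never fatal. Spontaneous-report data are
  dirty, and a pipeline that aborts on the first unknown code does not
  survive contact with a real quarter.

Writing is the exact inverse of reading: `writeQuarter()` emits files
that round-trip byte-identically. Because FAERS itself has no escaping
convention, a field value containing the `'$'` separator is rejected at
write time rather than silently corrupted.

## Cohorts, dictionaries and comparison designs

Drugs appear in FAERS as free text with dose and form suffixes
("TIGECYCLINE 50MG VIAL"). A drug dictionary maps a label to generic
and brand-name patterns, matched case-insensitively on word boundaries
against both the verbatim name and the active-ingredient field: exact
matching would silently lose cases, unbounded substring matching would
let short names match inside unrelated tokens. Events are matched by
exact, case-insensitive MedDRA preferred-term strings against an event
dictionary of named groups plus an umbrella group
(`coagulation_dysfunction`) that must contain every subgroup term. The
shipped dictionaries are documented best-effort defaults — they are not
licensed MedDRA content and are meant to be replaced by study-specific
files in production.

Cohort membership follows the primary-suspect convention: a case belongs
to a drug's cohort when at least one of its drug entries with role
`primary_suspect` matches the dictionary. All 2×2 cells are counted at
case level (one case, one count, regardless of how many matching PTs or
drug entries it carries), which is what a case-count signal threshold
refers to. Four comparator schemes are expressible: the full database
(every case whose primary suspect is not the target — excluding the
target's own reports is the conservative case/non-case reading and the
default), or a named drug set evaluated per drug or pooled. A case that
qualifies for both the target and a comparator is assigned to the target
and logged, so no cell is double-counted.

**Dose-regimen classification.** The descriptive table stratifies
tigecycline regimens, but FAERS has no regimen field, so a rule has to
be defined over dose entries. The maintenance dose is the modal
`dose_amt` over target-drug entries starting *after* the first therapy
date (falling back to all entries when therapy has a single date):
standard below 200 mg/day, high at 200 mg/day or above. A loading dose
is an earliest-date entry of at least 200 mg that is *also* at least
twice the maintenance modal dose. The second clause matters: a rule
keyed only on "≥ 200 mg on the first day" cannot distinguish a loading
dose from a high-maintenance regimen that simply runs at 200 mg/day from
day one. Loading/non-loading and standard/high maintenance are two
separate dichotomies; cases without usable dose entries stay
unclassified, so the regimen rows — like their real-world analogue — do
not sum to the cohort size.

## The estimator

With `a`/`b` the target cases with/without the event and `c`/`d` the
comparator analogues, the reporting odds ratio is `(a·d)/(b·c)` and the
95% interval is the Woolf log-normal interval
`exp(ln ROR ± z·sqrt(1/a + 1/b + 1/c + 1/d))` — the de-facto standard
in ROR pharmacovigilance. The z quantile for the default level is fixed
at 1.959964 so documented examples are stable to the printed precision.
A signal is `ROR ≥ 2.0` with `a ≥ 3` (both thresholds are arguments).
Zero cells make the ROR undefined; the default policy reports the table
as undefined (batch evaluation continues, the row is flagged), and the
alternative applies the Haldane–Anscombe +0.5 correction to all four
cells with `correction_applied` recorded in the result. No
multiple-testing adjustment is applied across event groups or designs;
that mirrors common practice in signal detection and is a known
limitation — the outputs are screening statistics, not confirmatory
tests.

## Descriptive analytics

`summarizeCohort()` splits the target cohort into the event arm and the
other-AE arm and tabulates sex, age (< 65 / ≥ 65 / missing), reporter
class, receipt-year bins (2005–2010, 2011–2015, 2016–2020 by default,
keyed on FDA receipt year), outcome codes and dose regimen, with arm
sizes as percentage denominators. Outcome rows are intentionally
non-exclusive — a FAERS case can carry several outcome codes — so their
percentages sum above 100 while every exclusive stratification
partitions its arm. The case-fatality rate is the death-outcome share of
the event arm. Subgroup contrasts use Pearson's chi-square on 2×2
tables without continuity correction, one degree of freedom.

Time to onset is the event date minus the *earliest* day-precision
therapy start of the target drug, in whole days; negative intervals
(event recorded before therapy start) are data-entry noise and are
excluded with a tally. The median and IQR use linear interpolation
between order statistics (type-7 quantiles, the default in most
scientific software and the rule implied by fractional published
quartiles); the cumulative onset curve is the fraction of records at or
below each integer day.

## The synthetic generator and what it does (not) show

`simulateFaers()` generates FAERS-shaped data with known truth: each
report draws a primary-suspect drug arm, event-group hits as independent
Bernoulli draws with configured probabilities (each hit emits one
uniformly chosen PT of that group plus one to three background PTs),
demographics and outcomes from configured mixes, and an onset time from
a gamma distribution added to a uniform therapy start. A configured
fraction of cases is emitted twice (same payload, new `primaryid`,
receipt 30 days later) to exercise deduplication, and a fraction of
event dates is truncated to month precision to exercise the
partial-date policy. Everything is driven by a single seed and is
byte-reproducible. `trueRor()` returns the odds ratio implied by the
configured probabilities — for the full-database comparator, the
report-count-weighted mixture over all non-target arms — so estimator
recovery is checkable without any external reference.

Default conditions: a target arm of 1,517 reports whose per-group
probabilities put the overall coagulation-event share near 14.7%, six
comparator antibiotic arms with probabilities chosen so their contrasts
with the target span below-null to strong signals, 20,000 background
reports, a 2005–2020 receipt window, 5% duplicate cases and 10% partial
event dates. The onset gamma (shape 4.4885, scale 2.3288 days) was fit
by least squares on the log-quantiles to a median of 10 days with IQR
6.75–13 — a two-parameter gamma cannot match all three quantiles
exactly, and after rounding to whole days this parameterisation gives
integer-day quartiles 7/10/13 with about 81% of onsets within 14 days,
the right-skewed profile typical of early-onset adverse reactions.
Dose-regimen fractions (21% loading, 21% high maintenance) follow the
classified shares of the published clinical-characteristics breakdown
this study design emulates.

The generator's independence assumptions are deliberate nulls: event
groups are drawn independently within a report, reporting rates are
constant over the window, and drug names are clean dictionary variants.
Real spontaneous data violate all three (correlated coagulation terms,
secular reporting trends and stimulated reporting, misspelled free-text
names). Passing the recovery and calibration tests therefore shows the
*machinery* is correct — counting, deduplication, matching, estimation
and intervals — not that any particular real-world signal is
reproduced. Scale is also reduced: validation runs use thousands of
reports per arm, not the tens of millions of a full 16-year FAERS
corpus, so headline estimates from the real corpus (for example the
extreme hypofibrinogenaemia disproportionality) are out of reach at desk
scale and are not asserted anywhere in the package.

## Validation summary

The test suite asserts, among others: byte-identical I/O round trips;
hand-computed ROR/CI oracles and exact reciprocity plus
comparator-scaling invariance; agreement of the estimator with an
independent log-scale computation on random tables; empirical 95%
interval coverage within [92%, 98%] over 600 simulated tables at true
RORs 1, 2 and 3.5 with 500 and 5,000 reports per arm; recovery of a
planted ROR of 3.5 (probabilities 0.28 vs 0.10) by the full pipeline
within 10% mean bias over 200 replicates at 5,000 reports per arm;
recovery of the configured onset median within one day at 2,000 reports
per arm; published-table arithmetic identities and chi-square p-values
reproduced exactly from printed counts; and byte-identical outputs of
two seeded pipeline runs. `scripts/acceptance.R` recomputes these
quantities from scratch against the installed package.

## Known limitations

* ROR only — PRR, information-component and empirical-Bayes shrinkage
  estimators are out of scope, as are duplicate-aware variance
  corrections.
* No MedDRA hierarchy traversal; event groups are flat PT sets, and the
  shipped lists are unlicensed approximations.
* Legacy (pre-2012Q4) AERS files, the XML dialect and INDI/RPSR tables
  are not read.
* Confounding by indication, comorbidity and co-medication is untouched:
  a signal is a reporting statistic, never a causal estimate.
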