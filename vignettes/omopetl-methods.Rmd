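---
title: "Methods: transforming multi-source EHR to the OMOP CDM and evaluating the result"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transforming multi-source EHR to the OMOP CDM and evaluating the result}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omopetl)
```

## The model of the conversion

`omopetl` treats an EHR-to-CDM conversion as two coupled mappings. The
*syntactic* mapping reshapes tables: patients become persons, encounters
become visit occurrences keyed by (encounter id, patient id, date), wide
laboratory rows become long measurement rows. The *semantic* mapping
sends every source code through a vocabulary: direct `maps-to` edges for
diagnosis/procedure terminologies, a two-hop chain for prescriptions
(prescription code `translates-to` a drug-dictionary concept, which
`maps-to` a standard drug concept — the chain succeeds only if **both**
hops exist), and an entity-field map for wide laboratory rows (one
measurement concept per populated, mapped field).

A phenotype is a set of per-terminology code lists plus the sources it
may draw on. Translating the lists through the vocabulary gives a
concept set; because several codes may map to one concept, translation
can collapse a list (and, symmetrically, a concept may capture codes
that were never listed). Executing the phenotype against the raw bundle
and against the CDM gives two patient sets whose differences the package
accounts for exactly:

* **unmapped patients** = source set \\ CDM set,
* **incorrectly mapped patients** = CDM set \\ source set,
* identity `cdm = original − unmapped + incorrect`, asserted on every
  concordance row.

The membership percentage columns use the respective cohort sizes as
denominators; the unmapped and incorrectly-mapped percentages use the
phenotype's own original and CDM counts. These are the only denominator
choices under which the package's reference concordance table (shipped
in `inst/extdata/`, from a published national UK heart-failure
conversion) reproduces its printed cells. The printed table itself mixes
rounding modes across cells (some cells are truncated, some rounded), so
the acceptance check asserts each percentage to within one unit in the
last printed digit while the identity on counts is exact;
`prevalence_pct()` itself rounds half-even.

## ETL rules and their rationale

* **Observation period**: start = max(registration date, practice
  up-to-standard date); end = min over the non-null of transfer-out,
  last collection, death, study end. A start after the end is treated as
  a defective record: the patient is rejected, never clamped, and every
  one of their rows is excluded with reason `rejected-patient`. Clamping
  would silently manufacture follow-up time.
* **Visits**: encounters without dates cannot be placed on a timeline
  and are excluded (`missing-date`). Visit ids are surrogate integers
  assigned in sorted-key order, so identical inputs give identical ids
  across runs. Hospital visit end dates are set equal to the admission
  date: discharge dates are not part of the source schema here, and an
  explicit equal-date convention is auditable.
* **Domain routing**: the resolved concept's domain chooses the target
  table. One-to-many resolutions emit one row per concept, all sharing
  one provenance pointer (source table, row, slot), so conservation
  stays auditable: per source table, distinct provenance pointers plus
  exclusion-ledger entries equal the source events. This is asserted
  after every run.
* **Events dated outside the observation period are retained** and only
  surfaced by the quality checks; dropping them would hide a data
  property behind the ETL. Events referencing an encounter that produced
  no visit (orphan rows, or rows pointing at an undated encounter) keep
  a null visit reference and are flagged rather than dropped.
* **Drug eras**: per (person, concept), exposures whose consecutive
  start dates lie within the era gap merge into one era ending at the
  last start plus the default prescription duration. Both default to 30
  days, the common convention for prescription data without explicit
  durations; both are parameters (`era_gap`, `drug_duration`, days).
* **Ethnicity** is taken exclusively from hospital records, even when
  primary care carries a value — mirroring conversions that trust the
  admission register for ethnicity. The comparison report computes
  ethnic-group percentages among patients with a *recorded* ethnicity in
  each representation, so the reported difference isolates cross-source
  disagreement rather than hospital coverage.
* The study end date defaults to 2016-03-08 and is configurable;
  sources disagree on such dates often enough that it must be a
  parameter.

## Cohort rules

Index = earliest phenotype event on/after 1998-01-01. Exclusions: age
under 18 at index, computed as index year minus year of birth (primary
care supplies year of birth only, so a year-resolution convention is
forced), and less than 365 days between observation-period start and
index, with the boundary inclusive (exactly 365 days qualifies — the
boundary is not defined by the prose rule "at least a year", so the
package fixes it explicitly). Follow-up ends at the observation-period
end, which is by construction the earliest of death, transfer-out, last
collection and study end. The rules commute: each is evaluated
independently, so the cohort is order-independent; the recorded reason
follows the fixed precedence no-index-event → no-observation-period →
under-age → insufficient-prior-registration.

Biomarker summaries use each included patient's first value on/after
index (median, type-7 IQR, mean, SD); ties on the first date break on
the value so both representations pick the same measurement. Smoking
uses a last-known-status-on-or-before-index rule over the status code
group. Medication rows report the percentage of the cohort with at
least one exposure in the class, to one decimal.

## What the generator emulates — and what it does not

The generator's defaults are the study conditions of the package's
acceptance suite: within-cohort frequencies of a national heart-failure
population (AF 0.35, COPD 0.50, T2DM 0.24, AMI 0.20, hypertension 0.66,
cancer 0.27; loop diuretics 0.42, ACE inhibitors 0.50, beta-blockers
0.48; 65%/31% smoker/never-smoker mix; 52.4% female; 90.8% majority
ethnicity with a 0.35% cross-source disagreement rate), heart failure
planted at 0.30 so the cohort is sizeable at n = 2000, blood-pressure
and BMI values drawn at the published cohort means/SDs
(143.07/22.42 mmHg systolic, 80.05/12.19 diastolic, 28.9/6.44 kg/m²),
and a 2% default rate for each planted defect mode — large enough to be
observable at desk scale. Source-table cardinalities per patient (a mean
of 8 consultations, Poisson event counts per phenotype) are not
constrained by any published value and were chosen once as plausible for
a 16-year primary-care window. Dates are day-granularity ISO-8601,
uniform within each patient's registration window.

Phenotype membership is drawn by independent Bernoulli trials; every
member receives at least one primary-care code, so membership flags stay
consistent with emitted codes. Defects are planted by row-level
Bernoulli draws from a *dedicated random stream per defect type*
(sub-seeded from the main seed), so changing one rate never reshuffles
another's rows — this is what makes exact recovery testing possible.
Unmappable-code defects are restricted to background (non-phenotype)
rows for the same consistency reason. Practice up-to-standard dates are
drawn at or before the study start, so inverted observation periods
occur exactly when planted.

The synthetic code systems are structurally realistic (prefixed,
fixed-width codes; a bijective code-to-concept map by default; unused
unmapped terms and broken drug chains in the vocabulary so term coverage
differs from event coverage) but self-contained: no licensed vocabulary
is used. The default bijection is deliberate — it makes the round-trip
theorem (defect-free bundle ⇒ identical source and CDM phenotype sets,
bit-equal biomarker summaries, all-zero quality counts) an exact
property, with `inject_many_to_one_mapping()` as the controlled
departure from it. Consequently, passing tests demonstrate the
*machinery* — conservation, rejection, flagging, set accounting — not
the messiness of real terminologies: real Read/ICD/drug dictionaries
have hierarchical, partially overlapping mappings, real missingness is
not Bernoulli, and real laboratory entity types number in the hundreds.
Full-scale coverage percentages and outside-period rates therefore
cannot be reproduced here; only the printed accounting identities are
checked against the published reference values.

## Numerical choices and degenerate inputs

Percentages round half-even at the stated precision (2 decimals for
membership, 1 for medication/lifestyle/quality rates); zero denominators
yield a flagged `NA` rather than an error. Date parsing is strict
ISO-8601 (a non-calendar date like 2016-02-30 becomes null and is
counted). Nulls are encoded as empty strings in the CSV dialect (comma,
double-quote escaping, UTF-8, LF). An entity row with all eight fields
empty produces nothing and counts nowhere; a populated `ignore-zero`
field holding `"0"` counts as an excluded (value-not-entered) event, not
an unmapped one — exclusions and unmapped events are disjoint classes by
design, because coverage reports them in separate columns. Unit-mapping
failures keep the measurement with a null unit concept; dropping a value
over its unit would lose information the conversion did not have to
lose. Tie-breaks: `max_prevalence_gap()` resolves equal gaps
alphabetically; visit surrogate ids follow sorted keys.

## Problem sizes

The acceptance suite runs the full pipeline at n = 2000 patients
(three ETL passes: defect-free, defect-planted, injection) and checks
operation-level behaviour against brute-force oracles on 210 randomized
small instances. Unit tests use 40–500 patients. One pipeline pass at
n = 2000 takes well under a minute on one CPU.

## Known limitations

Hospital spells carry no discharge date; prevalent versus incident case
handling beyond the index rule is not modelled; costs, providers,
care sites, specimens and free text are out of scope (as in the CDM
subset it mirrors); the ETL is single-shot by contract (re-running on
its own output is refused) rather than incremental; and the evaluation
performs descriptive comparison only — no hypothesis testing between
representations.
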