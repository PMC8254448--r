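---
title: "Auditing empiric antibiotic use from indication-registered EMR extracts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing empiric antibiotic use from indication-registered EMR extracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stewardaudit)
```

## The measurement problem

Antibiotic stewardship teams need to know how much antibiotic is used in
their hospital and how appropriate that use is. The classical instrument,
the point prevalence survey, reviews every chart by hand and is so
labour-intensive that most hospitals run it rarely and on small samples.
When the EMR *forces* the prescriber to register an indication with every
systemic antibiotic order — therapy class (empiric/targeted/prophylaxis),
focus of infection on tract level, and a sub-indication for respiratory
and urinary tract infections (RTI/UTI) — the appropriateness of empiric
therapy becomes computable from a flat extract. Two quantities then
matter:

* **accuracy** — how often the registered indication agrees with the
  diagnosis actually documented in the chart (if registration is sloppy,
  everything downstream is noise), and
* **appropriateness** — whether the empiric regimen matches the national
  first-choice (category **A**), second-choice (**B**) recommendations,
  or neither (**C**, discordant).

`stewardaudit` implements that pipeline end to end, together with a
synthetic-data generator so every stage is testable without access to
hospital data (real extracts are never publicly deposited).

## The empiric-therapy snapshot

Empiric therapy is defined by time, not by the registered class: febrile
patients are treated immediately, the regimen is adjusted as first
diagnostics arrive, and after about a day it either continues as the
settled empiric choice or becomes targeted therapy. The operational
definition is therefore:

* stays of **≥ 24 h**: the prescriptions *active* 24 hours after
  admission, with the half-open activity convention
  `start_ts <= t < stop_ts`. An absent stop means the prescription ran
  through discharge, and counts as active. A prescription stopping
  exactly at the snapshot instant is *not* active; one starting exactly
  then is. The source definition names the time point without boundary
  semantics; the half-open rule makes the snapshot unambiguous and is
  applied identically in the selection code, the test oracle and the
  generator.
* stays of **12–24 h**: the last prescribed therapy before discharge,
  operationalised as the record(s) with the maximal start time; ties are
  all kept, because simultaneously started antibiotics form a
  combination. Tie handling is undefined in the source; keeping all ties
  is the only choice that preserves combination regimens.
* stays **< 12 h** are not hospitalisations and are excluded upstream.

The snapshot clock starts at the ward admission timestamp
(`admit_ts`). Whether the original audit measured from ward admission or
hospital presentation is not decidable from the text; the admissions
table is authoritative here and the choice is recorded once, in this
section.

## Selection rules and flowchart accounting

Admission-level inclusion: age ≥ 18, general ward, stay ≥ 12 h, not a
readmission (a new admission starting within 30 days after the same
patient's previous discharge; only the *later* admission is excluded,
since guideline-recommended empiric treatment is usually not applicable
to it). Prescription-level exclusion: prophylaxis registrations (removed
before the snapshot), erroneous prescriptions whose start precedes the
admission, all RTI/UTI prescriptions of admissions carrying both an RTI
and a UTI regimen at the snapshot (they cannot be attributed to either
group), and configurable indication exclusion windows — the motivating
case being respiratory prescriptions after 2020-03-01, when no empiric
guideline for COVID-19 pneumonia existed. Windows key on the
*prescription start date* ("prescribed after"), not the admission date.

An admission failing several rules must be counted once, so exclusions
attribute to the **first failing rule in a fixed order**: age → ward →
stay → readmission, then prophylaxis class → snapshot → tract →
erroneous → dual-tract → window. Every stage satisfies
`input = kept + excluded` and consecutive stages telescope;
`render_flowchart()` refuses to render anything violating these
invariants. Targeted-registered prescriptions are *kept* by default —
the empiric definition is time-based — with
`exclude_indication_classes = c("prophylaxis", "targeted")` as the
opt-out. The dual-tract test uses the tract set captured at snapshot
time, before the erroneous-start removal, matching the field semantics
of the selection object.

A readmission gap of exactly the window length does not flag (strict
`<`); overlapping admissions of one patient warn and are resolved on
discharge order.

## Regimens and A/B/C classification

Antibiotics prescribed simultaneously for the same sub-indication are
one combination regimen; since the snapshot already guarantees
simultaneity, merging keys on `(admission_id, sub_indication)` with set
semantics over `(ATC code, route)` pairs. The guideline table maps each
sub-indication to first- and second-choice regimens as ATC-code sets, so
combination recommendations (ceftriaxone + ciprofloxacin for severe CAP)
are first-class. Matching is **exact set equality**, order- and
duplication-insensitive, with first choice tested before second:

* equality rather than subset because prescribing a recommended agent
  *plus* something extra is a different, broader-spectrum therapy — the
  stricter, auditable reading (`allow_extra_agents = TRUE` restores the
  laxer one);
* `route_strict` defaults to off because national recommendations are
  matched on agent identity; the flag exists because some
  recommendations are route-specific (oral nitrofurantoin for cystitis)
  and whether a wrong-route match should count as adherent is genuinely
  open.

The "other" sub-indications within RTI and UTI are heterogeneous
catch-alls and are never scored (`NOT_ASSESSED`). The **adherence rate**
defaults to A + B — one figure spanning both recommended tiers, which is
how a single published adherence percentage is built from a first-choice
and a second-choice agent share — configurable to A-only.

The packaged guideline file
(`inst/extdata/guideline_synthetic_swab_like.yaml`) is a synthetic,
illustrative stand-in consistent with common Dutch empiric practice
(amoxicillin/ceftriaxone appropriate for CAP, nitrofurantoin for
cystitis, ceftriaxone for complicated UTI, cefuroxime and
amoxicillin–clavulanate discordant for all three). Production audits
must supply the current national table; the reader validates it strictly
(unknown codes, duplicate regimens within or across tiers, assessable
entries without a first choice are all load-time errors).

## Validating registration accuracy

`draw_validation_sample()` draws a uniform without-replacement sample
per stratum — strata follow the *selected* indication: RTI, UTI, and a
`random_other` stratum that screens non-RTI/UTI registrations for missed
targets — returning the whole stratum as a flagged census when it is
smaller than requested. `compute_accuracy()` scores a review as an error
when selected ≠ documented **at sub-indication granularity**: selecting
cystitis for a documented pyelonephritis is an error even though the
tract matches, because classification keys on the sub-indication.
Reviews whose documentation was missing or inaccessible shrink the
denominator instead of counting as errors. Agreement and error always
sum to exactly 100%, and the overall rate pools stratum numerators and
denominators. `estimate_error_ci()` adds exact Clopper–Pearson intervals
(Beta-quantile closed form) for monitoring the error rate over repeated
validation rounds; the sampling unit is whatever identifier is supplied
and is named in the report.

## What the generator emulates — and what it does not

`sim_config()` defines the synthetic study conditions; its defaults are
fixed once and describe a plausible teaching-hospital year:

| parameter | default | what it sets |
|---|---|---|
| `n_patients` | 800 | ~1000 prescription rows per run |
| `tract_mix` | RTI .18 / UTI .12 / other .70 | ~30% RTI/UTI share, RTI ≈ 1.5 × UTI |
| `class_mix` | empiric .75 / targeted .15 / prophylaxis .10 | registration classes |
| `adherent_fraction` | 0.5 | P(regimen drawn from guideline tiers) |
| `first_choice_share` | 0.6 | P(first tier | adherent) |
| `misselection_rate` | 0.13 | per-prescription registration error |
| `underage/icu/short_stay/readmission` | .02/.05/.05/.08 | planted exclusions |
| `erroneous_start_fraction` | 0.02 | start-before-admission plants |
| `dual_tract_fraction` | 0.02 | RTI+UTI admissions |
| `boundary_stay_fraction` | 0.02 | stays of exactly 12 h or 24 h |

Length of stay is a mixture with explicit point masses *at* the 12 h and
24 h boundaries, precisely to stress the boundary semantics above.
The default confusion structure puts its dominant urinary mass on true
complicated UTI registered as cystitis — the characteristic error when
prescribers pick the milder diagnosis — plus respiratory
neighbour-confusions (CAP/COPD/bronchitis, severity swaps). One
pseudo-random stream is seeded once per run with a documented draw order
(admission anomalies, times, ages → episode class/tract/sub/adherence →
agent sets and timings in admission order → mis-selection), so outputs
are byte-identical for a given configuration.

Deliberate simplifications, hence what passing tests do *not* show about
real data: anomalies are planted mutually exclusively per patient (real
admissions fail several criteria at once — the attribution order is
tested separately on random instances, not via the generator); erroneous
starts are planted for whole regimens of clean empiric RTI/UTI
long-stay admissions, so their configured fraction applies to that
eligible population, and combinations are never half-removed;
mis-selection is independent per prescription, so a combination can end
up split across two registered sub-indications (as it can in a real
order-entry system); the default confusion never crosses tract
boundaries — with a custom cross-tract confusion, ground-truth exclusion
labels for dual-tract admissions may no longer match the pipeline's
attribution; no microbiology, dosing, allergy or free-text data is
modelled, and dose adequacy and treatment duration are out of scope
throughout the package.

## Numerical and degenerate-input choices

* Timestamps are a single timezone-naive timeline (POSIXct/UTC);
  date-only inputs parse at midnight, which the 12 h/24 h rules need.
* Proportions over {A, B, C} are exact rational arithmetic on counts;
  invariant checks use 1e-9 tolerances only where shares are summed.
* Empty selections are valid (an admission with nothing active at the
  snapshot); empty extracts produce all-zero flowcharts; an empty review
  table is an error rather than 100% agreement.
* Ties: simultaneous last prescriptions are all kept; a regimen matching
  two first-choice entries is A once; duplicate guideline entries are
  rejected at load, not silently deduplicated.
* Rare-combination pooling orders rows by descending frequency then
  lexicographically, so reports are reproducible across platforms.

## Interpreting a run

```{r example, eval = FALSE}
cohort <- generate_cohort(sim_config(seed = 1))
sel <- run_selection(cohort$prescriptions, cohort$admissions)
sel$flowchart
report <- adherence_summary(
  classify_regimens(assemble_regimens(sel$records), cohort$guideline))
report
accuracy <- compute_accuracy(simulate_chart_reviews(cohort))
accuracy
```

Because mis-selection is planted, the adherence computed on *registered*
sub-indications is biased (a correctly treated complicated UTI
registered as cystitis scores C); classifying on the ground-truth
sub-indication recovers the planted adherent fraction. That bias is the
package's core caveat for real audits too: verify registration accuracy
first, then read adherence, and treat sub-indications with high
confusion mass with suspicion.

## Test and simulation sizes

The suite exercises the selection against an independent brute-force
oracle on 200 random instances of up to 50 admissions, recovers planted
parameters over 100 seeded cohorts of ~1000 prescriptions each (99%
binomial intervals, ≥95% coverage required), and checks sampler
uniformity over 200 seeds; these sizes keep a full run around a minute
on one CPU while leaving the Monte-Carlo checks statistically
meaningful.

## Known limitations

Appropriateness here is agent-set adherence to a supplied guideline
table: treatment duration, dosing, allergy- or culture-driven deviations
(which a chart review would accept) all score as discordant.
Accuracy validation measures registration against documentation, not the
correctness of the diagnosis itself. Benchmarking across hospitals
compares adherence without case-mix adjustment. And hospitals configure
their EMRs differently — taxonomies may lack codes (no severity split
for CAP, no "other" option in a tract), which the taxonomy and
benchmark tooling tolerate but which shifts where errors and
discordance accumulate.
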