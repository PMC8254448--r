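# stewardaudit

Audit the extent and appropriateness of in-hospital antibiotic use from
EMR extracts with mandatory indication registration.

When the order-entry system forces prescribers to register, with every
systemic antibiotic (ATC class J01) prescription, an indication class
(empiric / targeted / prophylaxis), a focus tract, and — for respiratory
and urinary tract infections (RTI/UTI) — a sub-indication, the quality of
empiric prescribing becomes computable from a flat extract instead of a
hand-done point prevalence survey. `stewardaudit` is the pipeline for
that computation, aimed at antibiotic stewardship teams and surveillance
parties benchmarking hospitals:

1. **Ingest & validate** (`read_prescription_extract()`,
   `read_admissions()`, `validate_extract()`) — delimited extracts with
   per-hospital column/value maps; unparseable rows are returned as
   rejects with reasons, never dropped.
2. **Cohort selection** (`run_selection()`) — adults on general wards,
   hospitalised ≥ 12 h, readmissions within 30 days excluded; the
   empiric regimen is the therapy active at the 24-hour snapshot
   (`start ≤ t < stop`), or the last therapy before discharge for
   12–24 h stays. Every stage is accounted in a CONSORT-style flowchart
   with hard conservation checks (`input = kept + excluded`,
   consecutive stages telescope).
3. **Regimen assembly** (`assemble_regimens()`) — simultaneous
   prescriptions for one sub-indication merge into one combination
   regimen, the unit of appropriateness.
4. **A/B/C classification** (`classify_regimens()`,
   `adherence_summary()`, `benchmark_table()`) — exact agent-set
   matching against a structured guideline table: category **A** equals
   a first-choice recommendation, **B** a second-choice one, **C** is
   discordant; the adherence rate is A+B by default. Rare agent
   combinations pool into "other" below a 5% display share.
5. **Accuracy validation** (`draw_validation_sample()`,
   `compute_accuracy()`, `estimate_error_ci()`) — stratified chart-review
   sampling and the selected-vs-documented agreement arithmetic, with
   errors scored at sub-indication granularity and exact Clopper–Pearson
   intervals for monitoring.
6. **Synthetic cohorts** (`sim_config()`, `generate_cohort()`,
   `inject_misselection()`) — fully ground-truthed admissions,
   prescriptions and chart reviews, with planted exclusions, planted
   adherence and a configurable indication-confusion process, so the
   whole pipeline is testable without hospital data.

A thin command-line wrapper (`exec/stewardaudit`) exposes
`simulate`, `select`, `classify`, `validate-sample` and
`validate-score`.

## Worked example

```r
library(stewardaudit)

cohort <- generate_cohort(sim_config(seed = 1))   # ~1000 prescriptions
sel <- run_selection(cohort$prescriptions, cohort$admissions)
sel$flowchart
#>    stage             input  kept excluded
#>  1 unlinked           1009  1009        0
#>  2 age                1009   991       18
#>  3 ward                991   955       36
#>  4 stay                955   903       52
#>  5 readmission         903   833       70
#>  6 indication_class    833   755       78
#>  7 snapshot            755   755        0
#>  8 tract               755   262      493
#>  9 erroneous           262   259        3
#> 10 dual_tract          259   227       32
#> 11 indication_window   227   227        0
```

Of 1009 simulated J01 prescriptions, 227 survive as empiric RTI/UTI
therapy: 18 belonged to minors, 36 to ICU stays, 52 to sub-12 h stays,
70 to 30-day readmissions, 78 were prophylaxis registrations, 493 had
other indications, 3 started before admission and 32 sat on admissions
carrying both an RTI and a UTI regimen. Classification against the
packaged (synthetic, illustrative) guideline table then gives:

```r
report <- adherence_summary(
  classify_regimens(assemble_regimens(sel$records), cohort$guideline))
report
#> <adherence_report> 176 assessable regimen(s), 26 not assessed;
#>   overall adherence (AB) 42.0%
#>    sub_indication           n prop_A prop_B prop_C adherence_rate
#>  2 CAP-m                   24 0.0833 0       0.917         0.0833
#>  3 CAP-s                   23 0.391  0.0870  0.522         0.478
#>  9 complicated-UTI         29 0.345  0.172   0.483         0.517
#> 10 cystitis                21 0.143  0.143   0.714         0.286
#>    ...
```

The 227 kept prescriptions merged into 202 regimens (176 assessable plus
26 for non-assessed "other" sub-indications). The planted adherent
fraction was 0.50, yet the report shows 42%: the generator also plants a
13% indication mis-selection rate, and a correctly treated complicated
UTI registered as cystitis scores C. The chart-review workflow exposes
exactly that:

```r
accuracy <- compute_accuracy(simulate_chart_reviews(cohort))
accuracy
#> <accuracy_report> unit: prescription record
#>   stratum      n_screened n_unassessable n_errors error_rate_pct agreement_pct
#> 1 RTI                 218              0       34           15.6          84.4
#> 2 UTI                 128              0       21           16.4          83.6
#> 3 random_other        663              0        0            0           100
#> overall agreement 94.5% (error rate 55/1009)
```

so accuracy must be verified (and, if need be, prescriber feedback
given) before adherence numbers are benchmarked — which is the audit
method's central operating rule. Re-classifying on the ground-truth
sub-indications recovers the planted 50%.

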