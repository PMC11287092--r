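---
title: "Rules-based AESI phenotypes and their validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rules-based AESI phenotypes and their validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aesidetect)
```

## The detection algorithm

`aesidetect` implements a rules-based computable phenotype for postvaccination
adverse events of special interest (AESIs). The same composition algorithm is
reused for all five shipped phenotypes — myocarditis/pericarditis,
anaphylaxis, Guillain-Barré syndrome (GBS), thrombosis with thrombocytopenia
syndrome at unusual sites (TTS), and febrile seizure — with only the code
lists and a handful of parameters changing per condition:

1. **Index diagnosis.** A condition event with a code in the phenotype's
   diagnosis list and `diagnosis_role = final_or_discharge`. Admitting,
   working and other roles never qualify: they lack the specificity of the
   final determination of care.
2. **Care-setting filter.** The index encounter's grouped setting
   (inpatient / outpatient / emergency) must be in the phenotype's allowed
   set (e.g. GBS is inpatient-only; anaphylaxis excludes outpatient).
3. **Clean window.** The diagnosis must be the first known diagnosis of its
   type. Under the default all-history clean window, a patient whose
   qualifying diagnosis codes appear in more than one distinct encounter is
   excluded entirely as a possible chronic condition.
4. **Condition window.** Supporting evidence is searched in the union of the
   index encounter span and `[dx − 2, dx + 10]` days around the diagnosis.
5. **Supporting evidence.** A boolean ANY/ALL tree over medication,
   observation (laboratory/vital) and procedure code sets; a leaf is
   satisfied when at least one event of its category dated inside the
   condition window carries one of its codes. Febrile seizure ships with no
   evidence requirement.
6. **Vaccine exposure (optional).** When enabled, a qualifying immunization
   must precede (or coincide with) the diagnosis within a risk window. The
   shipped definitions leave this off — the validation design the package
   mirrors estimated operating characteristics on all detected cases, not
   just postvaccination ones — but `exposure_rule()` turns it on for
   surveillance use.

All temporal logic is at day granularity with closed intervals; the engine
contains no randomness and output ordering is fixed by patient identifier,
date and code, so identical inputs give byte-identical output.

### Decisions where the design was genuinely open

- **Condition-window anchoring.** "Two days before" could anchor to the
  encounter start or the diagnosis date. We take the union of the encounter
  span and the diagnosis-anchored window, which is never narrower than
  either reading.
- **What counts as an occurrence.** Only final/discharge diagnoses count
  toward the clean-window recurrence rule, for the same specificity reason
  they alone can be index events. Multiple qualifying codes inside the
  single index encounter are one occurrence — co-coded synonyms are not
  evidence of chronicity — and the earliest such date becomes the index
  date.
- **Per-patient deduplication.** A patient contributes at most one detected
  case per phenotype (the recurrence rule makes multi-encounter candidates
  chronic by definition).
- **Insufficient history.** A candidate whose index date leaves less than
  365 days of coverage behind it is excluded with its own attrition reason
  rather than passed; the validation design guaranteed a one-year lookback
  by pulling a historical year of data.
- **Evidence dates.** Evidence matching uses the event's own date, not its
  encounter's span.

## Shipped definitions and provenance

The myocarditis, pericarditis and TTS diagnosis lists are transcribed from
the validation study's published tables (`provenance: "published"`). The
anaphylaxis, GBS and febrile-seizure diagnosis lists, and all supporting
evidence lists, were published only through an external value-set registry;
the package ships structurally valid **placeholder** sets (marked
`provenance: "placeholder"`) so the full pipeline runs end-to-end. Replace
them with curated value sets before any real surveillance use — tooling can
refuse to over-claim fidelity by checking the provenance field.

Sensitivity-analysis variants are data, not code: removing a code set from
the evidence tree (myocarditis/pericarditis without NSAIDs, GBS without
gabapentin), restricting the diagnosis list (pericarditis-only,
myocarditis-only, TTS to I81 or its complement — each pair partitions its
base list), adding an evidence rule (febrile seizure with medication,
observation, either, or both), or adjusting only the adjudication
interpretation (the GBS case-definition relaxation), which never changes the
engine.

## The synthetic cohort generator

No patient-level data ship with the package, so the generator produces
EHR-shaped cohorts with known ground truth. Its defaults mirror the
validation study's frame: a surveillance period 2018-01-01 to 2022-05-01, a
historical year of coverage from 2017-01-01, and an era cutoff at
2020-12-11, the first US COVID-19 vaccine emergency use authorization (the
study never printed its cutoff; it is configurable).

Each patient–phenotype pair is independently planted as one of: a
`qualifying_case` satisfying every criterion; a `chronic_excluded` history
(the same diagnosis in two encounters); a `wrong_setting`, `wrong_role`, or
`missing_evidence` violation of exactly that one criterion (half of the
missing-evidence plants place their evidence strictly *outside* the
condition window, exercising the boundary). Background noise draws from
distractor code lists that are disjoint from every shipped code set by
construction, so on synthetic data a false positive is impossible by design
and any detection outside the planted qualifying set is a genuine engine
bug. The central integration test exploits this: on generated cohorts the
engine must recover exactly the planted qualifying cases, for every shipped
phenotype and every engine-affecting variant, and must match an independent
brute-force oracle that naively re-checks every rule.

Rates are not prescribed by the study (true AESI incidence there was of
order 10⁻⁴, far too sparse for compact test cohorts). Defaults were chosen
once as a realistic-but-testable compromise: `true_case_rate = 0.01`,
`chronic_contamination_rate = 0.005`, `evidence_completeness = 0.9`,
`wrong_role_rate = 0.05`, `wrong_setting_rate = 0.005`, two background
events per patient-year, and a 20/60/20 inpatient/outpatient/emergency mix.
The pseudo-random stream is split per patient (a fixed hash of cohort seed
and patient index), so enlarging a cohort never perturbs earlier patients.

What the generator does *not* emulate: clinically realistic longitudinal
trajectories, correlated comorbidity, coding drift over time, free-text
notes, or code lists that partially overlap a phenotype's sets the way real
distractors would. Passing tests therefore demonstrate the engine's logical
correctness against its stated rules, not the clinical performance of the
code lists on real data — that is precisely what chart-review validation is
for.

## Validation statistics

The validation design the package implements: per phenotype, a stratified
sample of up to 100 pre-era and 35 post-era detected cases (febrile seizure:
pre-era only), plus 20 + 7 blinded negative controls drawn from non-selected
encounters as a data-quality check (controls are excluded from PPV and
reported separately). Two clinicians rate each case on the 1–5 diagnostic
certainty scale; levels 1–2 are positive; a positive/negative disagreement
is settled by a third reviewer; "possible, insufficient evidence" is a
level-3 designation handled by two denominator policies. PPV is reported
both excluding insufficient-evidence cases from the denominator and
including them; the numerator is identical under both, so the
exclude-insufficient PPV always dominates.

Numerical choices:

- **Agresti–Coull interval** with `z = 1.959964` (not 2): with
  `n* = n + z²` and `p* = (x + z²/2)/n*`, the interval is
  `p* ± z·sqrt(p*(1−p*)/n*)`, clipped to [0, 1]. The study's printed
  intervals deviate from this standard construction by up to ~0.3
  percentage points (consistent with rounding or a minor variant), so
  regression tests compare intervals at ±0.5 points while point estimates
  are exact.
- **Coverage.** The interval is intentionally conservative near the
  boundaries: exact coverage at p = 0.1 or 0.9 with n ∈ {30, 100} is
  97.2–97.4%, while at p = 0.5 it is 94.3–95.7%. The empirical-coverage
  test therefore evaluates the 93–97% band pooled over the
  (p, n) grid (exact pooled value 96.5%), and only the lower bound per
  cell.
- **Display rounding** is half-up to one decimal (base `round()` rounds
  half to even); internal values are full precision.
- **Cohen κ** uses the 2×2 dichotomy table with marginal-product expected
  agreement; κ is flagged undefined (not forced to zero) when expected
  agreement is 1.
- **Two-sample proportion test** is the pooled-variance normal
  approximation, two-sided; zero pooled variance returns p = 1 with a
  degenerate flag.
- **No multiple-testing adjustment**: stratification and sensitivity
  analyses are exploratory.

Because the study published every numerator and denominator, its PPV tables
are recomputable at desk scale: `records_from_counts()` rebuilds a minimal
adjudication record set from each published (TP, total, sufficient) triple
and `replicate_study()` recomputes every displayed value through the same
`compute_ppv()` path used for fresh data. Two published cells are internally
inconsistent with their own counts (the febrile-seizure overall row prints
89 where its counts give 88.0, matching instead its emergency-department
column 73/82; one GBS combined-variant cell prints 57.1 where 49/86 gives
57.0); the package reports the count-derived values.

## Problem sizes and determinism

The test suite runs entirely on synthetic data built at test time: cohorts
of 70–300 patients for engine/oracle equivalence and label faithfulness
(about 200 patients is where the oracle's quadratic naivety starts to cost
more than it teaches), 6,000 binomial draws for interval coverage, and 200
replicates of 135-case adjudication sets for parameter recovery. All
randomness is seeded; the acceptance script takes a single `--seed` and
derives every stream from it.

## Known limitations

- Placeholder code lists (above) — the largest gap to real surveillance use.
- The FHIR NDJSON mapping is a documented convention over the seven
  resource types the engine consumes, not a general FHIR client; the
  diagnosis-role element in particular is carried in a named extension.
- Sensitivity, specificity and NPV are out of scope by design: estimating
  them requires validating an infeasibly large negative sample for rare
  events.
- Care-setting grouping from raw encounter types is the caller's
  responsibility (a config-level mapping), since source systems disagree on
  encounter-type vocabularies.
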