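# aesidetect

Rules-based computable phenotypes for detecting five adverse events of
special interest (AESIs) in EHR-shaped data — myocarditis/pericarditis,
anaphylaxis, Guillain-Barré syndrome (GBS), thrombosis with
thrombocytopenia syndrome at unusual sites (TTS), and febrile seizure —
together with the statistical machinery used to validate such algorithms by
clinician chart review. It is aimed at vaccine-safety surveillance teams
and informatics groups who need a phenotype engine that runs on flat,
interoperable coded data (ICD-10-CM / SNOMED-CT / RxNorm / NDC / CPT /
ICD-10-PCS / LOINC) without any NLP or vendor-specific logic.

## The algorithm

One composition algorithm is reused across all phenotypes; only code lists
and parameters change. For a patient with condition events *D*:

1. **Index diagnosis** — a final/discharge diagnosis *d ∈ D* whose code is
   in the phenotype's diagnosis value set.
2. **Care setting** — the index encounter's grouped setting must be allowed
   (GBS: inpatient only; anaphylaxis: inpatient or emergency).
3. **Clean window** — *d* must be the first known diagnosis of its type;
   qualifying codes in more than one distinct encounter exclude the patient
   as a possible chronic condition (default lookback: all history, with at
   least one year of coverage guaranteed before the index date).
4. **Condition window** — `[min(enc_start, d − 2 days),
   max(enc_end, d + 10 days)]`.
5. **Supporting evidence** — an ANY/ALL tree over medication, observation
   and procedure code sets, satisfied inside the condition window (febrile
   seizure: no evidence required).
6. **Vaccine exposure** *(optional, off by default)* — a qualifying
   immunization within a risk window ending at the index date.

Validation statistics: dual-denominator positive predictive value
(excluding or including "possible, insufficient evidence" level-3 cases),
Agresti–Coull 95% intervals (`n* = n + z²`, `p* = (x + z²/2)/n*`,
`p* ± z√(p*(1−p*)/n*)`), Cohen κ between the two primary reviewers, a
pooled two-sample proportion z-test, stratified sampling (100 pre-era + 35
post-era cases per phenotype) with blinded negative controls, and
two-reviewer adjudication with a third-reviewer tiebreak.

## Worked example

```r
library(aesidetect)

# a seeded synthetic cohort with known ground truth
cfg <- generator_config(500, seed = 42, true_case_rate = 0.02)
cohort <- generate_cohort(cfg)

cases <- detect(cohort$bundle, get_definition("myocarditis_pericarditis"))
cases[, c("patient_id", "index_date", "care_setting", "code", "n_evidence")]
#> # A tibble: 11 × 5
#>    patient_id index_date care_setting code   n_evidence
#>    <chr>      <date>     <chr>        <chr>       <int>
#>  1 P000024    2021-02-21 outpatient   I30.8           1
#>  2 P000061    2018-05-29 outpatient   I40.0           1
#>  3 P000158    2018-11-14 emergency    I30.9           1
#>  ...

attrition(cases)
#> # A tibble: 5 × 2
#>   filter                  n
#>   <chr>               <int>
#> 1 index_diagnosis        14
#> 2 care_setting           14
#> 3 clean_window           14
#> 4 supporting_evidence    11
#> 5 exposure               11
```

Fourteen patients had a qualifying final/discharge diagnosis; all were in
allowed care settings with clean histories, three lacked supporting
evidence inside the condition window, and eleven cases were detected —
exactly the generator's planted qualifying cases.

Simulated chart review and PPV:

```r
rec <- generate_adjudication_truth(cases$patient_id, ppv_target = 0.835,
                                   insufficiency_rate = 0.2, seed = 42)
compute_ppv(adjudicate(rec), "exclude_insufficient")
#> <validation_result> exclude_insufficient: 6/10 = 60.0% (31.2%-83.3%)
compute_ppv(adjudicate(rec), "include_all")
#> <validation_result> include_all: 6/11 = 54.5% (28.0%-78.7%)
```

(With 11 cases the interval is wide; the point of the validation design is
to run this at 100+ cases per phenotype.)

The published validation counts for the shipped phenotypes are themselves
package data, and every displayed PPV is recomputable from them:

```r
rep <- replicate_study()
rep[rep$analysis == "overall",
    c("phenotype", "tp", "n_all", "n_sufficient", "ppv_sufficient", "ppv_all")]
#> # A tibble: 5 × 6
#>   phenotype                   tp n_all n_sufficient ppv_sufficient ppv_all
#>   <chr>                    <int> <int>        <int>          <dbl>   <dbl>
#> 1 myocarditis_pericarditis    86   135          103           83.5    63.7
#> 2 anaphylaxis                 98   135          105           93.3    72.6
#> 3 gbs                         34   110           72           47.2    30.9
#> 4 tts                         87   135          124           70.2    64.4
#> 5 febrile_seizure             73   100           83           88      73
```

A command-line interface wraps the same functions
(`inst/cli/aesidetect simulate|detect|sample|stats|replicate-study`); every
run writes a JSON manifest recording its inputs and seed.

## Caveats

The myocarditis, pericarditis and TTS diagnosis code lists are transcribed
from the published validation tables; the remaining diagnosis lists and all
supporting-evidence lists are clearly marked placeholders (the study
published them only through an external value-set registry) and must be
replaced with curated value sets before real surveillance use. See the
methods vignette (`vignettes/phenotype-validation.Rmd`) for the full model
description, design decisions, and limitations.
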