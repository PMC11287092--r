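# Sensitivity-analysis variants, keyed by base phenotype.  A variant either
# removes an evidence code set, restricts the diagnosis code list, adds an
# evidence rule, or only adjusts how adjudicators interpret the case
# definition (which never changes the detection engine).
myocarditis_pericarditis:
  no_nsaids:
    modification: remove_code_set
    payload: [nsaid_meds]
  pericarditis_only:
    modification: restrict_diagnosis_codes
    payload: [pericarditis_dx]
  myocarditis_only:
    modification: restrict_diagnosis_codes
    payload: [myocarditis_dx]
gbs:
  no_gabapentin:
    modification: remove_code_set
    payload: [gabapentin_meds]
  adjusted_case_definition:
    modification: adjusted_adjudication_criteria
    payload: >-
      Accept a neurologist consult or general clinical-note evidence of the
      diagnosis in place of missing reflex documentation or CSF WBC counts.
febrile_seizure:
  medication_evidence:
    modification: add_evidence_rule
    payload: {any: [antipyretic_meds]}
  observation_evidence:
    modification: add_evidence_rule
    payload: {any: [seizure_fever_obs]}
  either_evidence:
    modification: add_evidence_rule
    payload: {any: [antipyretic_meds, seizure_fever_obs]}
  both_evidence:
    modification: add_evidence_rule
    payload: {all: [antipyretic_meds, seizure_fever_obs]}
tts:
  i81_only:
    modification: restrict_diagnosis_codes
    payload: [tts_i81_dx]
  non_i81:
    modification: restrict_diagnosis_codes
    payload: [tts_other_dx]
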