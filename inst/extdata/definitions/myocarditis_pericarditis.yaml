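# Combined myocarditis/pericarditis phenotype.  Any-of supporting evidence:
# troponin labs, NSAIDs, other treatment medications, or cardiac procedures.
name: myocarditis_pericarditis
allowed_care_settings: [inpatient, outpatient, emergency]
clean_window_days: all
condition_window_pre_days: 2
condition_window_post_days: 10
diagnosis_code_sets: [myocarditis_dx, pericarditis_dx]
evidence_rule:
  any: [troponin_lab, nsaid_meds, cardiac_meds, cardiac_procedures]
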