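# Guillain-Barre syndrome: inpatient-only index diagnoses.
name: gbs
allowed_care_settings: [inpatient]
clean_window_days: all
condition_window_pre_days: 2
condition_window_post_days: 10
diagnosis_code_sets: [gbs_dx]
evidence_rule:
  any: [ivig_meds, gabapentin_meds, csf_labs, plasmapheresis_procedures]
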