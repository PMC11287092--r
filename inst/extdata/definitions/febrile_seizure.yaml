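# Febrile seizure: no supporting-evidence requirement in the base algorithm.
name: febrile_seizure
allowed_care_settings: [inpatient, outpatient, emergency]
clean_window_days: all
condition_window_pre_days: 2
condition_window_post_days: 10
diagnosis_code_sets: [febrile_seizure_dx]
evidence_rule: null
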