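# Thrombosis with thrombocytopenia syndrome at unusual sites.
name: tts
allowed_care_settings: [inpatient, outpatient, emergency]
clean_window_days: all
condition_window_pre_days: 2
condition_window_post_days: 10
diagnosis_code_sets: [tts_i81_dx, tts_other_dx]
evidence_rule:
  any: [platelet_lab, tts_meds, tts_procedures]
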