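# Anaphylaxis phenotype: index diagnoses in inpatient or emergency settings,
# supported by epinephrine administration or a tryptase result.
name: anaphylaxis
allowed_care_settings: [inpatient, emergency]
clean_window_days: all
condition_window_pre_days: 2
condition_window_post_days: 10
diagnosis_code_sets: [anaphylaxis_dx]
evidence_rule:
  any: [epinephrine_meds, tryptase_lab]
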