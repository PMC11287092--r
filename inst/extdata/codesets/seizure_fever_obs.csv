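system,code,description,provenance
LOINC,8310-5,Body temperature,placeholder
LOINC,8661-1,Chief complaint - Reported,placeholder
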