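system,code,description,provenance
LOINC,777-3,Platelets [#/volume] in Blood by Automated count,placeholder
LOINC,26515-7,Platelets [#/volume] in Blood,placeholder
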