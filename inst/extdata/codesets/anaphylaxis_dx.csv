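system,code,description,provenance
ICD-10-CM,T78.0,Anaphylactic shock due to adverse food reaction,placeholder
ICD-10-CM,T78.2,"Anaphylactic shock, unspecified",placeholder
ICD-10-CM,T80.5,Anaphylactic reaction due to serum,placeholder
ICD-10-CM,T88.6,Anaphylactic reaction due to adverse effect of correct drug,placeholder
SNOMED-CT,39579001,Anaphylaxis,placeholder
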