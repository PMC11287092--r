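system,code,description,provenance
ICD-10-CM,R56.00,"Simple febrile convulsions",placeholder
ICD-10-CM,R56.01,"Complex febrile convulsions",placeholder
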