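system,code,description,provenance
ICD-10-CM,I81,Portal vein thrombosis,published
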