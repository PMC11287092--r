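system,code,description,provenance
LOINC,2880-3,Protein [Mass/volume] in Cerebral spinal fluid,placeholder
LOINC,806-0,Leukocytes [#/volume] in Cerebral spinal fluid,placeholder
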