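system,code,description,provenance
LOINC,6598-7,Troponin T cardiac [Mass/volume] in Serum or Plasma,placeholder
LOINC,10839-9,Troponin I cardiac [Mass/volume] in Serum or Plasma,placeholder
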