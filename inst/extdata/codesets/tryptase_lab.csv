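system,code,description,provenance
LOINC,21582-2,Tryptase [Mass/volume] in Serum or Plasma,placeholder
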