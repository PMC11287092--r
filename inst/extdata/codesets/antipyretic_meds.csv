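system,code,description,provenance
RxNorm,161,Acetaminophen,placeholder
RxNorm,5640,Ibuprofen,placeholder
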