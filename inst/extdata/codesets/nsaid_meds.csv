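system,code,description,provenance
RxNorm,5640,Ibuprofen,placeholder
RxNorm,7258,Naproxen,placeholder
RxNorm,1191,Aspirin,placeholder
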