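system,code,description,provenance
RxNorm,15202,Argatroban,placeholder
RxNorm,60819,Bivalirudin,placeholder
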