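system,code,description,provenance
RxNorm,2683,Colchicine,placeholder
RxNorm,8640,Prednisone,placeholder
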