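system,code,description,provenance
CPT,70450,CT head or brain without contrast,placeholder
CPT,70496,CT angiography head,placeholder
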