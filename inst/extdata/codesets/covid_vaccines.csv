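system,code,description,provenance
NDC,59267-1000-1,COVID-19 mRNA vaccine (synthetic stand-in NDC),placeholder
NDC,80777-273-10,COVID-19 mRNA vaccine (synthetic stand-in NDC),placeholder
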