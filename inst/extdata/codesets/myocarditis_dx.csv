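system,code,description,provenance
ICD-10-CM,I40.0,Infective myocarditis,published
ICD-10-CM,I40.1,Isolated myocarditis,published
ICD-10-CM,I40.8,Other acute myocarditis,published
ICD-10-CM,I40.9,"Acute myocarditis, unspecified",published
ICD-10-CM,I51.4,Viral myocarditis,published
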