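system,code,description,provenance
ICD-10-CM,B33.22,Viral pericarditis,published
ICD-10-CM,B33.23,Acute rheumatic pericarditis,published
ICD-10-CM,I30.0,Acute nonspecific idiopathic pericarditis,published
ICD-10-CM,I30.1,Infective pericarditis,published
ICD-10-CM,I30.8,Other forms of acute pericarditis,published
ICD-10-CM,I30.9,"Acute pericarditis, unspecified",published
ICD-10-CM,I32,Pericarditis in diseases classified elsewhere,published
ICD-10-CM,I41,Meningococcal pericarditis,published
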