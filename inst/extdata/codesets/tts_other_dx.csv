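system,code,description,provenance
ICD-10-CM,G08,Intracranial and intraspinal phlebitis and thrombophlebitis,published
ICD-10-CM,I82.0,Budd-Chiari syndrome,published
ICD-10-CM,I82.3,Embolism and thrombosis of renal vein,published
ICD-10-CM,I82.890,Acute embolism and thrombosis of other specified veins,published
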