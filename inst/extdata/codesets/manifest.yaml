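# Registry of shipped code sets.  `provenance: published` marks lists
# transcribed from the validation study's result tables; `placeholder` marks
# structurally valid stand-ins for value sets published only through an
# external value-set registry -- replace them with curated lists before any
# real surveillance use.
myocarditis_dx:
  file: myocarditis_dx.csv
  category: diagnosis
  concept_label: acute myocarditis diagnoses
pericarditis_dx:
  file: pericarditis_dx.csv
  category: diagnosis
  concept_label: acute pericarditis diagnoses
anaphylaxis_dx:
  file: anaphylaxis_dx.csv
  category: diagnosis
  concept_label: anaphylactic reaction diagnoses
gbs_dx:
  file: gbs_dx.csv
  category: diagnosis
  concept_label: Guillain-Barre syndrome diagnoses
tts_i81_dx:
  file: tts_i81_dx.csv
  category: diagnosis
  concept_label: portal vein thrombosis (I81)
tts_other_dx:
  file: tts_other_dx.csv
  category: diagnosis
  concept_label: other unusual-site thrombosis diagnoses
febrile_seizure_dx:
  file: febrile_seizure_dx.csv
  category: diagnosis
  concept_label: febrile convulsion diagnoses
troponin_lab:
  file: troponin_lab.csv
  category: observation
  concept_label: cardiac troponin laboratory results
nsaid_meds:
  file: nsaid_meds.csv
  category: medication
  concept_label: nonsteroidal anti-inflammatory drugs
cardiac_meds:
  file: cardiac_meds.csv
  category: medication
  concept_label: myocarditis/pericarditis treatment medications
cardiac_procedures:
  file: cardiac_procedures.csv
  category: procedure
  concept_label: cardiac diagnostic procedures
epinephrine_meds:
  file: epinephrine_meds.csv
  category: medication
  concept_label: epinephrine administration
tryptase_lab:
  file: tryptase_lab.csv
  category: observation
  concept_label: serum tryptase laboratory results
ivig_meds:
  file: ivig_meds.csv
  category: medication
  concept_label: intravenous immune globulin
gabapentin_meds:
  file: gabapentin_meds.csv
  category: medication
  concept_label: gabapentin
csf_labs:
  file: csf_labs.csv
  category: observation
  concept_label: cerebrospinal fluid laboratory results
plasmapheresis_procedures:
  file: plasmapheresis_procedures.csv
  category: procedure
  concept_label: therapeutic plasma exchange
platelet_lab:
  file: platelet_lab.csv
  category: observation
  concept_label: platelet count laboratory results
tts_meds:
  file: tts_meds.csv
  category: medication
  concept_label: non-heparin anticoagulants
tts_procedures:
  file: tts_procedures.csv
  category: procedure
  concept_label: thrombosis imaging procedures
antipyretic_meds:
  file: antipyretic_meds.csv
  category: medication
  concept_label: fever-reducing medications
seizure_fever_obs:
  file: seizure_fever_obs.csv
  category: observation
  concept_label: fever or seizure-related observations
covid_vaccines:
  file: covid_vaccines.csv
  category: immunization
  concept_label: COVID-19 vaccine administrations
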