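# Default condition -> search-term lexicon for free-text comparison.
# Terms are plain words; they are lowercased and Porter-stemmed at use time,
# so "hypertension" here also matches "hypertensive" in responses.
# Edit freely: mappings may be many-to-one (several terms, one condition).
"Ischaemic heart disease": [heart, cardiac, cardiovascular, angina, coronary]
"Female breast cancer": [breast]
"Trachea, bronchus, lung cancer": [lung]
"Suicide": [suicide, suicidal]
"Kidney disease, renal failure": [kidney, renal]
"Lymphomas, multiple myeloma": [lymphoma, myeloma]
"Diabetes": [diabetes, diabetic]
"Mouth, oesophagus, and gastric cancer": [mouth, oesophagus, esophagus, gastric, stomach]
"Premature birth": [premature, preterm]
"Dementia": [dementia, alzheimers, alzheimer]
"Mental and behavioral disorders": [mental, depression, anxiety, behavioral]
"Leukaemia": [leukaemia, leukemia]
"COPD": [copd, emphysema, bronchitis]
"Cervical cancer": [cervical, cervix]
"Cerebrovascular disease": [stroke, cerebrovascular]
"Prostate cancer": [prostate]
"Colorectal cancer": [bowel, colorectal, colon]
"Pancreatic cancer": [pancreas, pancreatic]
"Asthma": [asthma, asthmatic]
"Hypertensive disease": [hypertension, hypertensive]
"HIV/AIDS": [hiv, aids]
"Melanoma of skin": [melanoma, skin]
"Gestational diabetes": [gestational]
"Motor vehicle accidents": [accident, crash, road]
"Peptic ulcer disease": [ulcer, peptic]
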