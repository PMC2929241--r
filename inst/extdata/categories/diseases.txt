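# diseases and disorders
leukemia
lymphoblastic leukemia
lymphoma
carcinoma
sarcoma
melanoma
diabetes
anemia
asthma
hypertension
osteoporosis
alzheimer
parkinson
schizophrenia
epilepsy
fibrosis
arthritis
obesity
stroke
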