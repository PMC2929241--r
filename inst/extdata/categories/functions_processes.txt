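# biological functions and processes
neurogenesis
segmentation
apoptosis
adhesion
proliferation
differentiation
phosphorylation
oligomerization
transcription
repression
activation
migration
osteogenesis
angiogenesis
regeneration
thermotolerance
diapedesis
transmigration
localization
secretion
coagonist
racemase
kinase
transferase
exonuclease
methylation
ubiquitination
splicing
translation
replication
recombination
chemotaxis
endocytosis
exocytosis
autophagy
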