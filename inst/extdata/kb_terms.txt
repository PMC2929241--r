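# Default knowledge-base phrase list (controlled-vocabulary seed terms
# drawn from ontology-style sources). One phrase per line; exact surface
# match on token boundaries. Replace or extend via the kb_terms config.
wd40
wrpw
eh1
zinc finger
leucine zipper
homeodomain
transcriptional corepressor
transcriptional repressor
transcriptional activation
programmed cell death
cell cycle
cell adhesion
signal transduction
ion transport
tight junction
heat shock protein
serine racemase
nmda receptor
growth factor
stem cell
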