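# Category scheme: vocabulary files, word endings (suffixes) and cue words
# per category. Primary categories precede secondary ones; assignment is
# first match wins, Unclassified is the fallback. This is a small curated
# default, fully replaceable by pointing the pipeline at another scheme.
categories:
  - name: Functions and Processes
    kind: primary
    vocab: [functions_processes.txt]
    suffixes: [genesis, lysis, ylation]
    cues: []
  - name: GO Related Terms
    kind: primary
    vocab: [go_terms.txt]
    suffixes: []
    cues: []
  - name: Domains and Motifs
    kind: primary
    vocab: [domains_motifs.txt]
    suffixes: []
    cues: [domain, motif, repeat, finger]
  - name: Pathways and Signaling
    kind: primary
    vocab: [pathways.txt]
    suffixes: []
    cues: [pathway, signaling, signalling, cascade]
  - name: Diseases
    kind: primary
    vocab: [diseases.txt]
    suffixes: [oma, emia, itis, pathy]
    cues: [disease, syndrome, cancer, tumor, tumour]
  - name: Gene (Family) Names
    kind: secondary
    vocab: [gene_names.txt]
    suffixes: []
    cues: []
  - name: Drugs and Chemical Compounds
    kind: secondary
    vocab: [drugs.txt]
    suffixes: []
    cues: [inhibitor, agonist, antagonist]
  - name: Species Names
    kind: secondary
    vocab: [species_names.txt]
    suffixes: []
    cues: []
  - name: Anatomical Parts
    kind: secondary
    vocab: [anatomy.txt]
    suffixes: []
    cues: [tissue]
  - name: Cells, Cell Types, and Cell Lines
    kind: secondary
    vocab: [cells.txt]
    suffixes: [cyte, blast]
    cues: [cell, cells]
  - name: Techniques and Treatments
    kind: secondary
    vocab: [techniques.txt]
    suffixes: []
    cues: [assay, staining, microscopy, knockout, treatment]
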