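# species and organism names
human
mouse
mice
rat
zebrafish
drosophila
xenopus
chicken
bovine
porcine
yeast
arabidopsis
caenorhabditis elegans
escherichia coli
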