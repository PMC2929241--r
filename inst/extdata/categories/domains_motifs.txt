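# protein domains and sequence motifs
wd40
wrpw
eh1
homeodomain
bromodomain
chromodomain
zinc finger
leucine zipper
helix-loop-helix
ww3 domain
sh2
sh3
ankyrin
kringle
immunoglobulin fold
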