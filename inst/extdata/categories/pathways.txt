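# pathways and signaling systems
wnt
notch
hedgehog
mapk
jak-stat
nf-kb
tgf-beta
mitochondrial pathway
apoptotic pathway
insulin signaling
calcium signaling
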