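# gene and gene-family names
bmp
bmp2
fezf1
fezf2
groucho
hdac
foxp2
bax
bad
apaf1
p53
p27
kip1
myc
ras
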