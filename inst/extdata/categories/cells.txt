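# cells, cell types and cell lines
lymphocyte
leukocyte
neuron
fibroblast
osteoclast
osteoblast
macrophage
hela
hek293
keratinocyte
erythrocyte
platelet
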