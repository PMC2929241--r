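# terms drawn from GO-style controlled vocabulary
programmed cell death
signal transduction
cell cycle
cell adhesion
ion transport
dna binding
protein folding
cell division
cellular permeability
cellular thermotolerance
gene expression
chromatin remodeling
protein transport
oxidative stress
immune response
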