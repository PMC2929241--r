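# anatomical parts and tissues
brain
forebrain
retina
liver
kidney
heart
lung
bone
muscle
skin
pancreas
spleen
thymus
cartilage
dentin
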