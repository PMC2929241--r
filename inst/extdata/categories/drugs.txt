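# drugs and chemical compounds
tamoxifen
cisplatin
doxorubicin
rapamycin
glutamate
d-serine
dexamethasone
retinoic acid
lipopolysaccharide
nocodazole
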