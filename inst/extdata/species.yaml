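# Species labels and their aliases, matched in title, abstract body or
# MeSH descriptors. Editable configuration.
Homo sapiens:
  - homo sapiens
  - human
  - humans
Gallus gallus:
  - gallus gallus
  - chicken
  - chickens
  - chick
Bos taurus:
  - bos taurus
  - bovine
  - cattle
  - cow
  - cows
Mus musculus:
  - mus musculus
  - mouse
  - mice
  - murine
Sus scrofa:
  - sus scrofa
  - pig
  - pigs
  - porcine
  - swine
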