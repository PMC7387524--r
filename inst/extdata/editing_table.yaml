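# Default editing-mechanism table: which ligands each editing aaRS
# proofreads against. Approximation of the editing survey literature,
# restricted to targets inside the 22-ligand vocabulary. MetRS and LysRS
# edit non-proteinogenic targets (homocysteine, ornithine) that have no
# ligand code and are therefore omitted here. Fully user-configurable:
# pass your own file to load_editing_table().
IleRS: [Val]
LeuRS: [Ile, Met]
ValRS: [Thr, Ala, Cys]
AlaRS: [Gly, Ser]
ThrRS: [Ser]
ProRS: [Ala, Cys]
PheRS: [Tyr]
SerRS: [Thr]
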