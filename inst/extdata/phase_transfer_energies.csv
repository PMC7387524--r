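# Phase-transfer free energies of amino-acid side-chain analogs (kcal/mol),
# after Radzicka & Wolfenden (1988), Biochemistry 27:1664-1670.
# dG_water_cyclohexane: transfer water -> cyclohexane;
# dG_vapor_cyclohexane: transfer vapor -> cyclohexane (thermodynamic cycle
# vapor -> water -> cyclohexane). Proline was not measured; its entries are
# interpolated from chemically similar nonpolar side chains (approximate).
residue,dG_water_cyclohexane,dG_vapor_cyclohexane
Ala,1.81,3.75
Arg,-14.92,-34.84
Asn,-6.64,-16.32
Asp,-8.72,-19.67
Cys,1.28,0.04
Gln,-5.54,-14.92
Glu,-6.81,-17.01
Gly,0.94,3.33
His,-4.66,-14.93
Ile,4.92,7.07
Leu,4.92,7.20
Lys,-5.55,-15.07
Met,2.35,0.87
Phe,2.98,2.22
Pro,0.50,-1.50
Ser,-3.40,-8.46
Thr,-2.57,-7.45
Trp,2.33,-3.55
Tyr,-0.14,-6.25
Val,4.04,6.03
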