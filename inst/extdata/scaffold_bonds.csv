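ligand,from,to
Ala,N,CA
Ala,CA,C
Ala,C,O
Ala,CA,CB
Arg,N,CA
Arg,CA,C
Arg,C,O
Arg,CA,CB
Arg,CB,CG
Arg,CG,CD
Arg,CD,NE
Arg,NE,CZ
Arg,CZ,NH1
Arg,CZ,NH2
Asn,N,CA
Asn,CA,C
Asn,C,O
Asn,CA,CB
Asn,CB,CG
Asn,CG,OD1
Asn,CG,ND2
Asp,N,CA
Asp,CA,C
Asp,C,O
Asp,CA,CB
Asp,CB,CG
Asp,CG,OD1
Asp,CG,OD2
Cys,N,CA
Cys,CA,C
Cys,C,O
Cys,CA,CB
Cys,CB,SG
Gln,N,CA
Gln,CA,C
Gln,C,O
Gln,CA,CB
Gln,CB,CG
Gln,CG,CD
Gln,CD,OE1
Gln,CD,NE2
Glu,N,CA
Glu,CA,C
Glu,C,O
Glu,CA,CB
Glu,CB,CG
Glu,CG,CD
Glu,CD,OE1
Glu,CD,OE2
Gly,N,CA
Gly,CA,C
Gly,C,O
His,N,CA
His,CA,C
His,C,O
His,CA,CB
His,CB,CG
His,CG,ND1
His,CG,CD2
His,ND1,CE1
His,CE1,NE2
His,NE2,CD2
Ile,N,CA
Ile,CA,C
Ile,C,O
Ile,CA,CB
Ile,CB,CG1
Ile,CB,CG2
Ile,CG1,CD1
Leu,N,CA
Leu,CA,C
Leu,C,O
Leu,CA,CB
Leu,CB,CG
Leu,CG,CD1
Leu,CG,CD2
Lys,N,CA
Lys,CA,C
Lys,C,O
Lys,CA,CB
Lys,CB,CG
Lys,CG,CD
Lys,CD,CE
Lys,CE,NZ
Met,N,CA
Met,CA,C
Met,C,O
Met,CA,CB
Met,CB,CG
Met,CG,SD
Met,SD,CE
Phe,N,CA
Phe,CA,C
Phe,C,O
Phe,CA,CB
Phe,CB,CG
Phe,CG,CD1
Phe,CG,CD2
Phe,CD1,CE1
Phe,CD2,CE2
Phe,CE1,CZ
Phe,CE2,CZ
Pro,N,CA
Pro,CA,C
Pro,C,O
Pro,CA,CB
Pro,CB,CG
Pro,CG,CD
Pro,CD,N
Pyl,N,CA
Pyl,CA,C
Pyl,C,O
Pyl,CA,CB
Pyl,CB,CG
Pyl,CG,CD
Pyl,CD,CE
Pyl,CE,NZ
Pyl,NZ,C2
Pyl,C2,O2
Pyl,C2,CA2
Pyl,CA2,CB2
Pyl,CB2,CG2
Pyl,CG2,CD2
Pyl,CD2,N2
Pyl,N2,CA2
Pyl,CB2,CE2
Sep,N,CA
Sep,CA,C
Sep,C,O
Sep,CA,CB
Sep,CB,OG
Sep,OG,P
Sep,P,O1P
Sep,P,O2P
Sep,P,O3P
Ser,N,CA
Ser,CA,C
Ser,C,O
Ser,CA,CB
Ser,CB,OG
Thr,N,CA
Thr,CA,C
Thr,C,O
Thr,CA,CB
Thr,CB,OG1
Thr,CB,CG2
Trp,N,CA
Trp,CA,C
Trp,C,O
Trp,CA,CB
Trp,CB,CG
Trp,CG,CD1
Trp,CG,CD2
Trp,CD1,NE1
Trp,NE1,CE2
Trp,CE2,CD2
Trp,CD2,CE3
Trp,CE3,CZ3
Trp,CZ3,CH2
Trp,CH2,CZ2
Trp,CZ2,CE2
Tyr,N,CA
Tyr,CA,C
Tyr,C,O
Tyr,CA,CB
Tyr,CB,CG
Tyr,CG,CD1
Tyr,CG,CD2
Tyr,CD1,CE1
Tyr,CD2,CE2
Tyr,CE1,CZ
Tyr,CE2,CZ
Tyr,CZ,OH
Val,N,CA
Val,CA,C
Val,C,O
Val,CA,CB
Val,CB,CG1
Val,CB,CG2
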