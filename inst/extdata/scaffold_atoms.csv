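ligand,atom_id,element,role
Ala,N,N,backbone
Ala,CA,C,backbone
Ala,C,C,backbone
Ala,O,O,backbone
Ala,CB,C,side_chain
Arg,N,N,backbone
Arg,CA,C,backbone
Arg,C,C,backbone
Arg,O,O,backbone
Arg,CB,C,side_chain
Arg,CG,C,side_chain
Arg,CD,C,side_chain
Arg,NE,N,side_chain
Arg,CZ,C,side_chain
Arg,NH1,N,side_chain
Arg,NH2,N,side_chain
Asn,N,N,backbone
Asn,CA,C,backbone
Asn,C,C,backbone
Asn,O,O,backbone
Asn,CB,C,side_chain
Asn,CG,C,side_chain
Asn,OD1,O,side_chain
Asn,ND2,N,side_chain
Asp,N,N,backbone
Asp,CA,C,backbone
Asp,C,C,backbone
Asp,O,O,backbone
Asp,CB,C,side_chain
Asp,CG,C,side_chain
Asp,OD1,O,side_chain
Asp,OD2,O,side_chain
Cys,N,N,backbone
Cys,CA,C,backbone
Cys,C,C,backbone
Cys,O,O,backbone
Cys,CB,C,side_chain
Cys,SG,S,side_chain
Gln,N,N,backbone
Gln,CA,C,backbone
Gln,C,C,backbone
Gln,O,O,backbone
Gln,CB,C,side_chain
Gln,CG,C,side_chain
Gln,CD,C,side_chain
Gln,OE1,O,side_chain
Gln,NE2,N,side_chain
Glu,N,N,backbone
Glu,CA,C,backbone
Glu,C,C,backbone
Glu,O,O,backbone
Glu,CB,C,side_chain
Glu,CG,C,side_chain
Glu,CD,C,side_chain
Glu,OE1,O,side_chain
Glu,OE2,O,side_chain
Gly,N,N,backbone
Gly,CA,C,backbone
Gly,C,C,backbone
Gly,O,O,backbone
His,N,N,backbone
His,CA,C,backbone
His,C,C,backbone
His,O,O,backbone
His,CB,C,side_chain
His,CG,C,side_chain
His,ND1,N,side_chain
His,CD2,C,side_chain
His,CE1,C,side_chain
His,NE2,N,side_chain
Ile,N,N,backbone
Ile,CA,C,backbone
Ile,C,C,backbone
Ile,O,O,backbone
Ile,CB,C,side_chain
Ile,CG1,C,side_chain
Ile,CG2,C,side_chain
Ile,CD1,C,side_chain
Leu,N,N,backbone
Leu,CA,C,backbone
Leu,C,C,backbone
Leu,O,O,backbone
Leu,CB,C,side_chain
Leu,CG,C,side_chain
Leu,CD1,C,side_chain
Leu,CD2,C,side_chain
Lys,N,N,backbone
Lys,CA,C,backbone
Lys,C,C,backbone
Lys,O,O,backbone
Lys,CB,C,side_chain
Lys,CG,C,side_chain
Lys,CD,C,side_chain
Lys,CE,C,side_chain
Lys,NZ,N,side_chain
Met,N,N,backbone
Met,CA,C,backbone
Met,C,C,backbone
Met,O,O,backbone
Met,CB,C,side_chain
Met,CG,C,side_chain
Met,SD,S,side_chain
Met,CE,C,side_chain
Phe,N,N,backbone
Phe,CA,C,backbone
Phe,C,C,backbone
Phe,O,O,backbone
Phe,CB,C,side_chain
Phe,CG,C,side_chain
Phe,CD1,C,side_chain
Phe,CD2,C,side_chain
Phe,CE1,C,side_chain
Phe,CE2,C,side_chain
Phe,CZ,C,side_chain
Pro,N,N,backbone
Pro,CA,C,backbone
Pro,C,C,backbone
Pro,O,O,backbone
Pro,CB,C,side_chain
Pro,CG,C,side_chain
Pro,CD,C,side_chain
Pyl,N,N,backbone
Pyl,CA,C,backbone
Pyl,C,C,backbone
Pyl,O,O,backbone
Pyl,CB,C,side_chain
Pyl,CG,C,side_chain
Pyl,CD,C,side_chain
Pyl,CE,C,side_chain
Pyl,NZ,N,side_chain
Pyl,C2,C,side_chain
Pyl,O2,O,side_chain
Pyl,CA2,C,side_chain
Pyl,CB2,C,side_chain
Pyl,CG2,C,side_chain
Pyl,CD2,C,side_chain
Pyl,N2,N,side_chain
Pyl,CE2,C,side_chain
Sep,N,N,backbone
Sep,CA,C,backbone
Sep,C,C,backbone
Sep,O,O,backbone
Sep,CB,C,side_chain
Sep,OG,O,side_chain
Sep,P,P,side_chain
Sep,O1P,O,side_chain
Sep,O2P,O,side_chain
Sep,O3P,O,side_chain
Ser,N,N,backbone
Ser,CA,C,backbone
Ser,C,C,backbone
Ser,O,O,backbone
Ser,CB,C,side_chain
Ser,OG,O,side_chain
Thr,N,N,backbone
Thr,CA,C,backbone
Thr,C,C,backbone
Thr,O,O,backbone
Thr,CB,C,side_chain
Thr,OG1,O,side_chain
Thr,CG2,C,side_chain
Trp,N,N,backbone
Trp,CA,C,backbone
Trp,C,C,backbone
Trp,O,O,backbone
Trp,CB,C,side_chain
Trp,CG,C,side_chain
Trp,CD1,C,side_chain
Trp,CD2,C,side_chain
Trp,NE1,N,side_chain
Trp,CE2,C,side_chain
Trp,CE3,C,side_chain
Trp,CZ2,C,side_chain
Trp,CZ3,C,side_chain
Trp,CH2,C,side_chain
Tyr,N,N,backbone
Tyr,CA,C,backbone
Tyr,C,C,backbone
Tyr,O,O,backbone
Tyr,CB,C,side_chain
Tyr,CG,C,side_chain
Tyr,CD1,C,side_chain
Tyr,CD2,C,side_chain
Tyr,CE1,C,side_chain
Tyr,CE2,C,side_chain
Tyr,CZ,C,side_chain
Tyr,OH,O,side_chain
Val,N,N,backbone
Val,CA,C,backbone
Val,C,C,backbone
Val,O,O,backbone
Val,CB,C,side_chain
Val,CG1,C,side_chain
Val,CG2,C,side_chain
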