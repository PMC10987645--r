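type,description
C.3,sp3 carbon
C.2,sp2 carbon
C.1,sp carbon
C.ar,aromatic carbon
C.cat,carbocation (guanidinium) carbon
N.3,sp3 nitrogen
N.2,sp2 nitrogen
N.1,sp nitrogen
N.ar,aromatic nitrogen
N.am,amide nitrogen
N.pl3,trigonal planar nitrogen
N.4,quaternary nitrogen
O.3,sp3 oxygen
O.2,sp2 oxygen
O.co2,carboxylate/phosphate oxygen
S.3,sp3 sulfur
S.2,sp2 sulfur
S.o,sulfoxide sulfur
S.o2,sulfone sulfur
P.3,sp3 phosphorus
F,fluorine
Cl,chlorine
Br,bromine
I,iodine
H,hydrogen
generic,unknown element or combination
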