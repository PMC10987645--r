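# Default library-preparation rules: drug-like descriptor windows plus a
# representative set of structural-alert SMARTS (reactive groups, common
# PAINS motifs, aggregator/autofluorescer chemotypes). Edit freely; the
# package validates every pattern at load time.
provenance: >-
  atomscreen default rule set: Lipinski/lead-like property windows and a
  ~30-pattern alert subset representative of published medicinal-chemistry
  filter collections (reactive/electrophilic groups, PAINS-A motifs,
  aggregation- and fluorescence-prone chemotypes).
property_ranges:
  - {descriptor: mw,              min: 250, max: 500}
  - {descriptor: clogp,           min: -2,  max: 5}
  - {descriptor: hbd,             min: 0,   max: 5}
  - {descriptor: hba,             min: 0,   max: 10}
  - {descriptor: rotatable_bonds, min: 0,   max: 10}
  - {descriptor: tpsa,            min: 0,   max: 140}
alert_patterns:
  # reactive / electrophilic
  - {name: acyl_halide,        smarts: "[CX3](=O)[F,Cl,Br,I]"}
  - {name: aldehyde,           smarts: "[CX3H1](=O)[#6]"}
  - {name: michael_acceptor,   smarts: "[CX3]=[CX3][CX3](=O)[!N]"}
  - {name: epoxide_aziridine,  smarts: "[OX2r3,NX3r3]1[#6r3][#6r3]1"}
  - {name: alkyl_halide,       smarts: "[CX4][Br,I]"}
  - {name: isocyanate,         smarts: "[NX2]=C=[OX1,SX1]"}
  - {name: anhydride,          smarts: "[CX3](=O)[OX2][CX3](=O)"}
  - {name: sulfonyl_halide,    smarts: "S(=O)(=O)[F,Cl,Br,I]"}
  - {name: thiol,              smarts: "[SX2H1]"}
  - {name: peroxide,           smarts: "[OX2][OX2]"}
  - {name: hydrazine,          smarts: "[NX3][NX3H2]"}
  - {name: azide,              smarts: "[NX2]=[NX2+]=[NX1-]"}
  - {name: diazonium,          smarts: "[NX2+]#[NX1]"}
  - {name: nitroso,            smarts: "[NX2]=[OX1]"}
  - {name: n_oxide_acyclic,    smarts: "[NX3+][OX1-]"}
  # nitro and nitro-aromatics (assay interference, mutagenicity flags)
  - {name: nitro,              smarts: "[N+](=O)[O-]"}
  - {name: polynitro_aromatic, smarts: "c([N+](=O)[O-])c[N+](=O)[O-]"}
  # PAINS-style motifs (representative A-list subset)
  - {name: rhodanine,          smarts: "S1C(=O)NC(=O)C1"}
  - {name: ene_rhodanine,      smarts: "S1C(=S)NC(=O)C1=C"}
  - {name: catechol,           smarts: "c1cc(O)c(O)cc1"}
  - {name: hydroxyphenyl_hydrazone, smarts: "c(O)c/C=N/N"}
  - {name: quinone,            smarts: "O=C1C=CC(=O)C=C1"}
  - {name: naphthoquinone,     smarts: "O=C1c2ccccc2C(=O)C=C1"}
  - {name: alkylidene_barbiturate, smarts: "C(=O)1NC(=O)NC(=O)C1=C"}
  - {name: azo_aromatic,       smarts: "c/N=N/c"}
  - {name: imine_of_phenol,    smarts: "c(O)ccC=N[!N]"}
  - {name: mannich_phenol,     smarts: "c(O)c(CN(C)C)"}
  # aggregation / autofluorescence prone
  - {name: anthraquinone_core, smarts: "O=C1c2ccccc2C(=O)c2ccccc21"}
  - {name: acridine,           smarts: "c1ccc2nc3ccccc3cc2c1"}
  - {name: polyene_chain,      smarts: "C=CC=CC=CC=C"}
  - {name: long_alkyl_chain,   smarts: "[CH2][CH2][CH2][CH2][CH2][CH2][CH2][CH2]"}
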