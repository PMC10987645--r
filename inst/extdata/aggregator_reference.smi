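Oc1ccc(cc1)/C=C/c1cc(O)cc(O)c1 agg_resveratrol
O=C(c1ccccc1)/C=C/c1ccc(O)c(O)c1 agg_chalcone1
Oc1cc(O)c2c(c1)oc(-c1ccc(O)c(O)c1)c(O)c2=O agg_quercetin
Clc1ccc(cc1)C(c1ccc(Cl)cc1)(c1ccc(Cl)cc1)O agg_triarylmethanol
O=C1c2ccccc2C(=O)c2ccccc21 agg_anthraquinone
Oc1ccc2ccccc2c1/N=N/c1ccccc1 agg_azo1
O=C(O)c1ccccc1-c1ccc2cc(O)ccc2c1 agg_biarylacid
CCCCCCCCCCCCc1ccc(cc1)S(=O)(=O)O agg_detergentlike
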