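"id","smiles","bits"
"fp01","c1ccccc1","651;963;974"
"fp02","CCO","139;242;440;579;588;670;861;894;991"
"fp03","CC(=O)Nc1ccccc1","29;32;55;169;219;322;323;345;361;391;398;425;438;522;526;594;651;670;899;963;974"
"fp04","[O-][N+](=O)c1ccccc1","6;29;98;139;206;248;304;322;440;475;522;526;585;596;651;963;974"
"fp05","CC(Cc1ccc(cc1)C(C(=O)O)C)C","6;18;29;55;139;210;298;322;323;334;366;382;416;437;438;497;511;514;522;555;560;600;651;670;714;732;838;874;977;991"
"fp06","CN1CCC[C@H]1c1cccnc1","29;111;113;146;185;250;285;322;354;476;491;575;585;620;626;649;651;670;685;704;716;753;775;808;810;842;920;954;963;999"
"fp07","NC(=O)c1ccccc1","29;40;134;165;197;322;323;325;401;438;482;522;526;543;651;812;963;974"
"fp08","OC(=O)c1ccccc1O","29;118;139;169;270;299;322;323;343;360;366;438;459;476;522;526;589;651;732;819;924;963"
"fp09","c1ccc2c(c1)cccc2","29;166;322;526;651;887;963;1005"
"fp10","OC(=O)c1ccc(cc1)Cl","29;44;139;246;322;323;343;360;366;438;476;482;522;534;555;580;651;701;822;934;1013"
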