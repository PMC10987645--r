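"id","smiles","mw","clogp","hbd","hba","rotatable_bonds","tpsa"
"lig00001","N#COc1ccccc1",119.1207,1.54648,0,2,1,33.02
"lig00002","NC(=O)c1ccccc1",121.13658,1.4858,1,2,1,43.09
"lig00003","O=C(c1cscc1)C1CCCCC1",194.29326,3.5111,0,1,2,45.31
"lig00004","O=C(c1ccccn1)c1ccncc1",184.19402,1.7076,0,3,2,42.85
"lig00005","C1CCC(CC1)CCc1cscc1",194.33632,4.261,0,0,3,28.24
"lig00006","FNC(=O)c1ccccn1",140.1151032,1.0868,1,3,2,41.99
"lig00007","CCOc1ccccc1",122.1644,2.0853,0,1,2,9.23
"lig00008","C1CCN(CC1)C=Cc1ccncc1",188.26884,2.4761,0,2,2,16.13
"lig00009","CCCN1CCCCC1",127.22728,1.8202,0,1,2,3.24
"lig00010","NNc1cocc1",98.10324,1.3385,2,2,1,51.19
"lig00011","CC(C(=O)c1cscc1)C",154.2294,2.5868,0,1,2,45.31
"lig00012","FCCc1c[nH]cc1",113.1328232,1.5267,1,0,2,15.79
"lig00013","OC(=O)Oc1ccccn1",139.1088,1.1384,1,4,2,59.42
"lig00014","COS(=O)(=O)c1cncnc1",174.17774,0.8925,0,5,2,77.53
"lig00015","Fc1ccccc1",96.1023032,1.8257,0,0,0,0
"lig00016","CN(CCc1cocc1)C",139.19492,1.3837,0,1,3,16.38
"lig00017","c1ccc(cc1)c1cscc1",160.23552,3.4151,0,0,1,28.24
"lig00018","FCCc1cscc1",130.1831832,2.2601,0,0,2,28.24
"lig00019","COC(=O)c1cocc1",126.11004,1.0662,0,2,2,39.44
"lig00020","OOc1cncnc1",112.08676,0.3284,1,4,1,55.24
"lig00021","NC(=O)Oc1ccccc1",137.13598,1.8444,1,3,2,52.32
"lig00022","O=S(=O)(C1CCCCC1)C1CCCCC1",230.36688,4.1474,0,2,2,42.52
"lig00023","O=C(c1ccccn1)NC1CCCCC1",204.26824,2.535,1,3,3,41.99
"lig00024","Nc1cncnc1",95.1026,0.64,1,3,0,51.8
"lig00025","OC(=O)NC(=O)c1c[nH]cc1",154.12344,0.8134,3,4,3,82.19
"lig00026","NCCc1ccccn1",122.1677,1.2831,1,2,2,38.91
"lig00027","FC(C=Cc1cocc1)(F)F",162.1092096,2.8551,0,0,2,13.14
"lig00028","CN(S(=O)(=O)c1c[nH]cc1)C",174.2208,1.3458,1,3,2,61.55
"lig00029","CC(Cc1ccccn1)C",135.20622,2.2801,0,1,2,12.89
"lig00030","CC(Nc1cscc1)C",141.23394,2.6414,1,1,2,40.27
"lig00031","OCc1ccccn1",109.12588,0.5739,1,2,1,33.12
"lig00032","NC(=O)NN1CCCCC1",143.18692,1.0847,2,4,2,58.36
"lig00033","CN(S(=O)(=O)N1CCCCC1)C",192.27914,1.2974,0,4,2,49
"lig00034","ClOC1CCCCC1",134.60394,2.4895,0,1,1,9.23
"lig00035","CN(NC(=O)c1ccccc1)C",164.20438,1.2839,1,3,3,32.34
"lig00036","CN(Cc1ccccn1)C",136.19428,1.1432,0,2,2,16.13
"lig00037","FC(=O)c1ccccn1",125.1004632,1.1913,0,2,1,29.96
"lig00038","OOc1c[nH]cc1",99.088,0.8665,2,2,1,45.25
"lig00039","OC(=O)CCc1c[nH]cc1",139.15186,1.0319,2,2,3,53.09
"lig00040","CCC=Cc1ccccn1",133.19034,2.5048,0,1,2,12.89
"lig00041","O=C(c1cncnc1)Nc1ccccc1",199.20866,1.8019,1,4,3,54.88
"lig00042","NC=Cc1c[nH]cc1",108.14112,1.6444,2,1,1,41.81
"lig00043","FC(Cc1ccccn1)(F)F",161.1244496,2.1864,0,1,2,12.89
"lig00044","C1CCC(CC1)CCc1ccccc1",188.3086,4.1995,0,0,3,0
"lig00045","ClCCc1ccccn1",141.59812,1.8629,0,1,2,12.89
"lig00046","FCOc1ccccn1",127.1163432,1.3874,0,2,2,22.12
"lig00047","CNC(=O)N1CCCCC1",142.19886,1.1405,1,3,2,32.34
"lig00048","NC(=O)C=Cc1cscc1",153.20158,1.9469,1,2,2,71.33
"lig00049","CNC(=O)c1ccccc1",135.16316,1.4371,1,2,2,29.1
"lig00050","C1CCC(CC1)Oc1cncnc1",178.23096,2.1881,0,3,2,35.01
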