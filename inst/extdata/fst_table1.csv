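group1,group2,fst,significant
E,G,0.0502,TRUE
E,K,0.0436,FALSE
E,O,0.0783,TRUE
E,PD,0.0971,TRUE
E,B,0.1621,TRUE
E,C,0.1374,TRUE
E,H,0.1375,TRUE
E,I,0.145,TRUE
E,M,0.1529,TRUE
E,P,0.1781,TRUE
E,R,0.1834,TRUE
E,T,0.1679,TRUE
E,V,0.1247,TRUE
G,K,0.0656,TRUE
G,O,0.0992,TRUE
G,PD,0.1128,TRUE
G,B,0.1299,TRUE
G,C,0.1375,TRUE
G,H,0.1293,TRUE
G,I,0.1233,TRUE
G,M,0.1183,TRUE
G,P,0.1569,TRUE
G,R,0.1515,TRUE
G,T,0.1433,TRUE
G,V,0.1294,TRUE
K,O,0.0705,FALSE
K,PD,0.1095,TRUE
K,B,0.1544,TRUE
K,C,0.138,TRUE
K,H,0.1513,TRUE
K,I,0.1505,TRUE
K,M,0.1353,TRUE
K,P,0.173,TRUE
K,R,0.1747,TRUE
K,T,0.1595,TRUE
K,V,0.1398,TRUE
O,PD,0.0584,TRUE
O,B,0.1222,TRUE
O,C,0.0756,FALSE
O,H,0.1152,TRUE
O,I,0.1013,TRUE
O,M,0.1032,TRUE
O,P,0.1535,TRUE
O,R,0.1436,TRUE
O,T,0.1041,TRUE
O,V,0.07,TRUE
PD,B,0.1345,TRUE
PD,C,0.1207,TRUE
PD,H,0.1262,TRUE
PD,I,0.1171,TRUE
PD,M,0.1385,TRUE
PD,P,0.1919,TRUE
PD,R,0.1909,TRUE
PD,T,0.1368,TRUE
PD,V,0.0997,TRUE
B,C,0.0502,TRUE
B,H,0.0529,TRUE
B,I,0.0438,TRUE
B,M,0.0533,TRUE
B,P,0.0972,TRUE
B,R,0.0659,TRUE
B,T,0.0453,FALSE
B,V,0.0475,TRUE
C,H,0.0629,TRUE
C,I,0.0351,TRUE
C,M,0.0246,FALSE
C,P,0.0647,TRUE
C,R,0.0643,TRUE
C,T,0.0405,TRUE
C,V,0.0364,TRUE
H,I,0.0193,FALSE
H,M,0.061,TRUE
H,P,0.1088,TRUE
H,R,0.0714,TRUE
H,T,0.0428,TRUE
H,V,0.0312,TRUE
I,M,0.0306,TRUE
I,P,0.0888,TRUE
I,R,0.056,TRUE
I,T,0.0163,FALSE
I,V,0.0299,TRUE
M,P,0.0638,FALSE
M,R,0.0671,TRUE
M,T,0.0171,FALSE
M,V,0.0517,TRUE
P,R,0.1123,TRUE
P,T,0.1002,TRUE
P,V,0.0911,TRUE
R,T,0.078,TRUE
R,V,0.0844,TRUE
T,V,0.0424,TRUE
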