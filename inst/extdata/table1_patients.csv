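patient_id,A0,alpha2,alpha3,patlak_Ki,kma3p_Ki,kma3p_kb,kma3p_Vb,k1_5p,k2_5p,k3_5p,k4_5p,ki_5p,kb_5p,vb_5p
1,10.82,0.1210,0.0122,0.0329,0.0312,0.0000,0.08,0.0418,0.154,0.3615,0.0000,0.0293,0.0000,0.06
2,9.16,0.2283,0.0134,0.0308,0.0312,0.0000,0.07,0.0893,0.952,0.4250,0.0000,0.0276,0.0000,0.00
3,9.57,0.1442,0.0126,0.0806,0.0845,0.0008,0.20,0.1059,0.033,0.1401,0.0000,0.0859,0.0000,0.07
4,9.69,0.1470,0.0144,0.0376,0.0391,0.0000,0.22,0.1371,0.834,0.3091,0.0000,0.0371,0.0000,0.02
5,8.28,0.1069,0.0096,0.0192,0.0198,0.0000,0.18,0.0667,0.780,0.3351,0.0000,0.0201,0.0000,0.04
6,9.55,0.1288,0.0148,0.0366,0.0390,0.0000,0.13,0.1025,0.684,0.3083,0.0000,0.0319,0.0000,0.01
7,19.79,0.2130,0.0154,0.0471,0.0560,0.0012,0.16,0.1079,0.892,0.6850,0.0000,0.0469,0.0000,0.03
8,16.26,0.1580,0.0128,0.0368,0.0384,0.0000,0.07,0.0802,1.000,0.7798,0.0000,0.0351,0.0000,0.03
9,53.45,0.2245,0.0193,0.0403,0.0446,0.0018,0.03,0.1240,1.000,0.4740,0.0000,0.0399,0.0000,0.03
10,16.46,0.1527,0.0171,0.0352,0.0360,0.0000,0.25,0.1045,0.616,0.3115,0.0000,0.0351,0.0000,0.04
11,12.45,0.1347,0.0141,0.0363,0.0358,0.0000,0.12,0.1394,1.000,0.2935,0.0000,0.0316,0.0000,0.03
12,15.14,0.1579,0.0116,0.0157,0.0202,0.0056,0.28,0.0962,0.610,0.1871,0.0099,0.0226,0.0076,0.05
13,22.17,0.1345,0.0141,0.0222,0.0249,0.0026,0.33,0.1374,0.601,0.1434,0.0043,0.0265,0.0035,0.03
14,22.41,0.1137,0.0141,0.0124,0.0135,0.0000,0.28,0.1173,0.777,0.1269,0.0071,0.0165,0.0061,0.02
15,18.61,0.2594,0.0187,0.0165,0.0171,0.0000,0.23,0.0837,0.470,0.1501,0.0044,0.0202,0.0034,0.07
16,21.40,0.1317,0.0155,0.0384,0.0389,0.0000,0.07,0.0375,0.000,0.5850,0.9596,0.0375,0.0000,0.05
17,13.53,0.1472,0.0153,0.0297,0.0266,0.0000,0.04,0.0319,0.099,0.4346,0.0000,0.0260,0.0000,0.07
18,17.28,0.1964,0.0144,0.0273,0.0323,0.0046,0.09,0.1161,1.000,0.3852,0.0031,0.0323,0.0022,0.05
19,12.26,0.1636,0.0160,0.0305,0.0314,0.0011,0.25,0.1329,0.549,0.2267,0.0052,0.0388,0.0037,0.10
20,9.37,0.1075,0.0140,0.0647,0.0643,0.0000,0.22,0.1561,0.417,0.3546,0.0000,0.0717,0.0000,0.13
21,8.26,0.1353,0.0143,0.1310,0.1450,0.0002,0.10,0.1503,0.123,1.0000,0.0000,0.1338,0.0000,0.08
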