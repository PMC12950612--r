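lambda_nm,medium,h_pct,ll_pct,mua_lm,nr_lm,ni_lm_e5,mua_bs
700,PBS,50,0,0.021,1.331,0.010,4.545
700,PBS,47,6,0.533,1.336,0.300,4.545
700,PBS,43,14,1.132,1.342,0.630,4.545
700,PBS,40,20,1.529,1.346,0.850,4.545
700,PBS,35,30,2.109,1.351,1.170,4.545
700,PLS,50,0,0.042,1.344,0.020,4.556
700,PLS,47,6,0.553,1.349,0.310,4.556
700,PLS,43,14,1.151,1.354,0.640,4.556
700,PLS,40,20,1.547,1.358,0.860,4.556
700,PLS,35,30,2.125,1.364,1.180,4.556
905,PBS,50,0,0.053,1.328,0.040,6.307
905,PBS,47,6,0.761,1.333,0.550,6.307
905,PBS,43,14,1.589,1.339,1.140,6.307
905,PBS,40,20,2.138,1.343,1.540,6.307
905,PBS,35,30,2.940,1.348,2.120,6.307
905,PLS,50,0,0.126,1.338,0.090,6.344
905,PLS,47,6,0.830,1.343,0.600,6.344
905,PLS,43,14,1.654,1.349,1.190,6.344
905,PLS,40,20,2.199,1.353,1.580,6.344
905,PLS,35,30,2.996,1.358,2.160,6.344
1000,PBS,50,0,0.464,1.327,0.370,4.861
1000,PBS,47,6,0.962,1.332,0.770,4.861
1000,PBS,43,14,1.544,1.338,1.230,4.861
1000,PBS,40,20,1.930,1.342,1.540,4.861
1000,PBS,35,30,2.494,1.348,1.980,4.861
1000,PLS,50,0,0.305,1.337,0.240,4.781
1000,PLS,47,6,0.812,1.342,0.650,4.781
1000,PLS,43,14,1.405,1.348,1.120,4.781
1000,PLS,40,20,1.797,1.352,1.430,4.781
1000,PLS,35,30,2.371,1.358,1.890,4.781
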