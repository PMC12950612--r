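lambda_nm,medium,ll_pct,qabs_e5,mua_bs,qsca,mus_bs,g
700,PBS,0,389.4,5.203,3.045,1017.2,0.991
700,PBS,6,387.8,4.870,2.927,1032.8,0.991
700,PBS,14,385.7,4.432,2.785,1040.9,0.992
700,PBS,20,384.2,4.107,2.689,1034.9,0.992
700,PBS,30,381.9,3.572,2.530,999.8,0.993
700,PLS,0,385.0,5.144,2.738,914.5,0.992
700,PLS,6,383.0,4.810,2.604,918.6,0.993
700,PLS,14,380.4,4.371,2.424,905.1,0.993
700,PLS,20,378.6,4.047,2.287,880.2,0.994
700,PLS,30,375.7,3.514,2.065,816.3,0.994
905,PBS,0,539.9,7.214,2.571,858.9,0.989
905,PBS,6,537.4,6.750,2.453,865.6,0.990
905,PBS,14,534.2,6.138,2.297,857.5,0.990
905,PBS,20,532.0,5.687,2.182,839.8,0.990
905,PBS,30,528.5,4.943,1.994,788.1,0.991
905,PLS,0,534.6,7.143,2.317,773.9,0.990
905,PLS,6,531.7,6.678,2.166,764.3,0.991
905,PLS,14,528.1,6.068,1.969,735.3,0.991
905,PLS,20,525.5,5.617,1.830,704.2,0.991
905,PLS,30,521.2,4.875,1.609,635.8,0.992
1000,PBS,0,399.4,5.337,2.461,822.0,0.988
1000,PBS,6,397.5,4.992,2.335,823.9,0.988
1000,PBS,14,395.0,4.539,2.170,810.0,0.989
1000,PBS,20,393.3,4.204,2.051,789.4,0.989
1000,PBS,30,390.6,3.654,1.859,734.6,0.990
1000,PLS,0,395.5,5.285,2.206,737.0,0.989
1000,PLS,6,393.3,4.940,2.050,723.3,0.989
1000,PLS,14,390.5,4.487,1.850,690.5,0.990
1000,PLS,20,388.6,4.154,1.711,658.6,0.990
1000,PLS,30,385.5,3.606,1.498,591.9,0.990
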