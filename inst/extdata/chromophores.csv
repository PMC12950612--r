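lambda_nm,eps_hbo,eps_hb,mua_water,nr_pbs,nr_pls,B,mua_pbs,mua_pls
700,290.0,1794.28,0.0060,1.331,1.344,12.8,0.021,0.042
905,1210.0,736.0,0.0730,1.328,1.338,12.8,0.053,0.126
1000,1030.0,206.0,0.3640,1.327,1.337,13.3,0.464,0.305
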