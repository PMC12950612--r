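lambda_nm,mua_rbc,nr_rbc,ni_rbc_e5
700,9.070,1.418,5.050
905,12.563,1.415,9.050
1000,9.258,1.417,7.370
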