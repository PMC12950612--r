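pair,medium,ll_pct,est_ll_pct,est_so2_pct
700-905,PBS,0,0.0,67.9
700-905,PBS,6,7.0,66.9
700-905,PBS,14,16.0,68.3
700-905,PBS,20,23.0,67.6
700-905,PBS,30,36.0,67.5
700-905,PLS,0,0.0,68.3
700-905,PLS,6,8.0,69.0
700-905,PLS,14,16.0,69.3
700-905,PLS,20,24.0,69.8
700-905,PLS,30,37.0,68.3
700-1000,PBS,0,0.0,70.5
700-1000,PBS,6,7.0,70.0
700-1000,PBS,14,18.0,69.8
700-1000,PBS,20,25.0,69.4
700-1000,PBS,30,38.0,68.8
700-1000,PLS,0,-1.0,70.3
700-1000,PLS,6,8.0,70.6
700-1000,PLS,14,18.0,69.9
700-1000,PLS,20,26.0,70.4
700-1000,PLS,30,36.0,70.7
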