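conc_mg_ml,rg,rg_err,rg_real_space
0.27,26.8,0.4,25.7
0.55,27.7,0.2,27.1
1.07,28.8,0.1,28.8
1.88,29.6,0.1,30.1
4.37,29.9,0.1,30.5
6.38,29.8,0.0,30.4
7.51,29.4,0.0,30.0
9.15,29.3,0.0,30.0
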