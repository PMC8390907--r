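b_molkg,density_gcm3
0.05,0.99946
0.1,1.00184
0.2,1.00655
0.3,1.01118
0.5,1.02026
0.75,1.03126
1,1.04192
1.25,1.05225
1.5,1.06227
2,1.08143
2.5,1.09951
3,1.1166
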