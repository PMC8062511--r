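stretch,nominal_stress_MPa
1,0
1.01,0.0023975617245834187
1.02,0.004873716588642393
1.03,0.007547708137165138
1.04,0.01053131506599915
1.05,0.013929413670229982
1.06,0.017840494346339688
1.07,0.022357136229177284
1.08,0.027566443651882173
1.09,0.03355044776479913
1.1,0.04038647633358388
1.11,0.04814749445310926
1.12,0.056902418658892374
1.13,0.06671640668848808
1.1400000000000001,0.07765112493884763
1.15,0.08976499547957581
1.16,0.10311342431424
1.17,0.11774901243034377
1.18,0.1337217510417328
1.19,0.15107920230340274
1.2,0.16986666666666642
1.21,0.19012733794117162
1.22,0.21190244703829833
1.23,0.23523139528703566
1.24,0.26015187813769286
1.25,0.2867000000000001
1.26,0.31491038089959067
1.27,0.34481625557993734
1.28,0.37644956562499976
1.29,0.4098410451306174
1.3,0.44502030040965007
1.31,0.4820158841765744
1.32,0.5208553646214216
1.33,0.5615653897501397
1.34,0.6041717473386026
1.35,0.6041717473386026
1.3599999999999999,0.6041717473386026
1.37,0.6041717473386026
1.38,0.6041717473386026
1.3900000000000001,0.6041717473386026
1.4,0.6041717473386026
1.4100000000000001,0.6041717473386026
1.42,0.6041717473386026
1.43,0.6041717473386026
1.44,0.6041717473386026
1.45,0.6041717473386026
1.46,0.6041717473386026
1.47,0.6041717473386026
1.48,0.6041717473386026
1.49,0.6041717473386026
1.5,0.6041717473386026
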