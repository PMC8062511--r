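stretch,nominal_stress_MPa
1,0
1.01,0.009590246898333675
1.02,0.01949486635456957
1.03,0.030190832548660552
1.04,0.0421252602639966
1.05,0.05571765468091993
1.06,0.07136197738535875
1.07,0.08942854491670914
1.08,0.11026577460752869
1.09,0.13420179105919652
1.1,0.16154590533433552
1.11,0.19258997781243703
1.12,0.2276096746355695
1.13,0.2668656267539523
1.1400000000000001,0.3106044997553905
1.15,0.35905998191830324
1.16,0.41245369725696
1.17,0.4709960497213751
1.18,0.5348870041669312
1.19,0.604316809213611
1.2,0.6794666666666657
1.21,0.7605093517646865
1.22,0.8476097881531933
1.23,0.9409255811481426
1.24,1.0406075125507714
1.25,1.1468000000000005
1.26,1.2596415235983627
1.27,1.3792650223197493
1.28,1.505798262499999
1.29,1.6393641805224697
1.3,1.7800812016386003
1.31,1.9280635367062977
1.32,2.0834214584856863
1.33,2.246261559000559
1.34,2.4166869893544103
1.35,2.4166869893544103
1.3599999999999999,2.4166869893544103
1.37,2.4166869893544103
1.38,2.4166869893544103
1.3900000000000001,2.4166869893544103
1.4,2.4166869893544103
1.4100000000000001,2.4166869893544103
1.42,2.4166869893544103
1.43,2.4166869893544103
1.44,2.4166869893544103
1.45,2.4166869893544103
1.46,2.4166869893544103
1.47,2.4166869893544103
1.48,2.4166869893544103
1.49,2.4166869893544103
1.5,2.4166869893544103
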