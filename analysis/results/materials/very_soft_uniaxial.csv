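stretch,nominal_stress_MPa
1,0
1.01,1.918049379666735e-4
1.02,3.8989732709139146e-4
1.03,6.038166509732111e-4
1.04,8.42505205279932e-4
1.05,0.0011143530936183986
1.06,0.001427239547707175
1.07,0.0017885708983341828
1.08,0.002205315492150574
1.09,0.002684035821183931
1.1,0.003230918106686711
1.11,0.003851799556248741
1.12,0.00455219349271139
1.13,0.005337312535079047
1.1400000000000001,0.006212089995107811
1.15,0.007181199638366066
1.16,0.0082490739451392
1.17,0.009419920994427502
1.18,0.010697740083338625
1.19,0.01208633618427222
1.2,0.013589333333333313
1.21,0.015210187035293731
1.22,0.016952195763063865
1.23,0.018818511622962854
1.24,0.02081215025101543
1.25,0.022936000000000012
1.26,0.025192830471967253
1.27,0.02758530044639499
1.28,0.030115965249999987
1.29,0.0327872836104494
1.3,0.035601624032772
1.31,0.038561270734125956
1.32,0.04166842916971373
1.33,0.04492523118001118
1.34,0.04833373978708821
1.35,0.04833373978708821
1.3599999999999999,0.04833373978708821
1.37,0.04833373978708821
1.38,0.04833373978708821
1.3900000000000001,0.04833373978708821
1.4,0.04833373978708821
1.4100000000000001,0.04833373978708821
1.42,0.04833373978708821
1.43,0.04833373978708821
1.44,0.04833373978708821
1.45,0.04833373978708821
1.46,0.04833373978708821
1.47,0.04833373978708821
1.48,0.04833373978708821
1.49,0.04833373978708821
1.5,0.04833373978708821
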