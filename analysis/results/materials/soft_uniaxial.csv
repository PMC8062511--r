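stretch,nominal_stress_MPa
1,0
1.01,8.391466036041965e-4
1.02,0.0017058008060248375
1.03,0.002641697848007798
1.04,0.003685960273099702
1.05,0.004875294784580494
1.06,0.00624417302121889
1.07,0.007824997680212048
1.08,0.00964825527815876
1.09,0.011742656717679698
1.1,0.014135266716754358
1.11,0.01685162305858824
1.12,0.01991584653061233
1.13,0.02335074234097083
1.1400000000000001,0.02717789372859667
1.15,0.03141774841785153
1.16,0.036089698509983996
1.17,0.04121215435062032
1.18,0.04680261286460648
1.19,0.05287772080619095
1.2,0.05945333333333325
1.21,0.06654456827941006
1.22,0.07416585646340441
1.23,0.08233098835046247
1.24,0.0910531573481925
1.25,0.10034500000000003
1.26,0.11021863331485673
1.27,0.12068568945297808
1.28,0.13175734796874994
1.29,0.14344436579571612
1.3,0.15575710514337748
1.31,0.16870555946180105
1.32,0.18229937761749754
1.33,0.1965478864125489
1.34,0.21146011156851088
1.35,0.21146011156851088
1.3599999999999999,0.21146011156851088
1.37,0.21146011156851088
1.38,0.21146011156851088
1.3900000000000001,0.21146011156851088
1.4,0.21146011156851088
1.4100000000000001,0.21146011156851088
1.42,0.21146011156851088
1.43,0.21146011156851088
1.44,0.21146011156851088
1.45,0.21146011156851088
1.46,0.21146011156851088
1.47,0.21146011156851088
1.48,0.21146011156851088
1.49,0.21146011156851088
1.5,0.21146011156851088
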