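stretch,nominal_stress_MPa
1,0
1.01,0.0011913504154721626
1.02,0.002378504898513351
1.03,0.0035807573749113398
1.04,0.0048174261619077195
1.05,0.006108419839927144
1.06,0.007474732108005154
1.07,0.008938874542513523
1.08,0.010525255491745496
1.09,0.012260513030870617
1.1,0.01417381002228682
1.11,0.01629709992120638
1.12,0.01866537307539703
1.13,0.02131689492483311
1.1400000000000001,0.024293449738443194
1.15,0.027640606351762124
1.16,0.03140802580605537
1.17,0.03564983484635284
1.18,0.040425093918682584
1.19,0.045798393618024624
1.2,0.05184061947786
1.21,0.05862993155732008
1.22,0.06625301246902857
1.23,0.07480664529493276
1.24,0.08439969125332426
1.25,0.09515554600219732
1.26,0.1072151630864574
1.27,0.12074074325392709
1.28,0.13592019917269582
1.29,0.15297251647579524
1.3,0.17215414403481524
1.31,0.19376655891899003
1.32,0.21816516462840968
1.33,0.2457696948979923
1.34,0.27707630965233615
1.35,0.31267158455070887
1.3599999999999999,0.3532486109976318
1.37,0.39962543950942325
1.38,0.4527661159235455
1.3900000000000001,0.513804577118973
1.4,0.5840716906860219
1.4100000000000001,0.6651257413480349
1.42,0.7587866859000401
1.43,0.8671745179972115
1.44,0.9927521043044475
1.45,1.1383728743153148
1.46,1.3073337675704355
1.47,1.50343386406061
1.48,1.731039146296089
1.49,1.9951538648694114
1.5,2.3014990033436176
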