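stretch,nominal_stress_MPa
1,0
1.01,0.0383609875933347
1.02,0.07797946541827828
1.03,0.12076333019464221
1.04,0.1685010410559864
1.05,0.22287061872367972
1.06,0.285447909541435
1.07,0.35771417966683655
1.08,0.44106309843011476
1.09,0.5368071642367861
1.1,0.6461836213373421
1.11,0.7703599112497481
1.12,0.910438698542278
1.13,1.0674625070158092
1.1400000000000001,1.242417999021562
1.15,1.436239927673213
1.16,1.64981478902784
1.17,1.8839841988855004
1.18,2.139548016667725
1.19,2.417267236854444
1.2,2.7178666666666627
1.21,3.042037407058746
1.22,3.3904391526127733
1.23,3.7637023245925705
1.24,4.162430050203086
1.25,4.587200000000002
1.26,5.038566094393451
1.27,5.517060089278997
1.28,6.023193049999996
1.29,6.557456722089879
1.3,7.120324806554401
1.31,7.712254146825191
1.32,8.333685833942745
1.33,8.985046236002235
1.34,9.666747957417641
1.35,9.666747957417641
1.3599999999999999,9.666747957417641
1.37,9.666747957417641
1.38,9.666747957417641
1.3900000000000001,9.666747957417641
1.4,9.666747957417641
1.4100000000000001,9.666747957417641
1.42,9.666747957417641
1.43,9.666747957417641
1.44,9.666747957417641
1.45,9.666747957417641
1.46,9.666747957417641
1.47,9.666747957417641
1.48,9.666747957417641
1.49,9.666747957417641
1.5,9.666747957417641
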