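design,diameter,plaque,mean,sem,n
MEGATRON_10,3.5,heterogeneous,3.3158043585123207,0.008863792475815837,4
MEGATRON_10,3.5,neutral,3.315393767067622,0.008982840553972063,4
MEGATRON_10,3.5,soft,3.3454637019921316,0.005385536550457719,4
MEGATRON_10,3.5,stiff,3.267323679882444,0.010852075735317341,4
MEGATRON_10,3.5,very_soft,3.363732594005566,0.0028857173446450424,4
MEGATRON_10,3.5,very_stiff,3.221527866303903,0.012857781726611077,4
MEGATRON_10,4.5,heterogeneous,4.084848758708705,0.0144910739516368,4
MEGATRON_10,4.5,neutral,4.057948489667481,0.018471013744111673,4
MEGATRON_10,4.5,soft,4.151134459314012,0.016847747105218452,4
MEGATRON_10,4.5,stiff,3.920754059158819,0.01979451970917038,4
MEGATRON_10,4.5,very_soft,4.234662160283392,0.01627150463095761,4
MEGATRON_10,4.5,very_stiff,3.7979652858275643,0.02027074124770436,4
MEGATRON_10,5,heterogeneous,4.382043802273829,0.0193113835122044,4
MEGATRON_10,5,neutral,4.325405993860159,0.0233735927438817,4
MEGATRON_10,5,soft,4.4473366414497395,0.021951263133550353,4
MEGATRON_10,5,stiff,4.150584909264704,0.023968943159949657,4
MEGATRON_10,5,very_soft,4.5520163303062855,0.020733268839230577,4
MEGATRON_10,5,very_stiff,4.014128658644772,0.0223641721122626,4
MEGATRON_12,3.5,heterogeneous,3.333689070311535,0.007941455306260071,4
MEGATRON_12,3.5,neutral,3.3322020661414484,0.008047316437617429,4
MEGATRON_12,3.5,soft,3.359871689182221,0.0047830406723316475,4
MEGATRON_12,3.5,stiff,3.2793583357262013,0.010193664617378074,4
MEGATRON_12,3.5,very_soft,3.3768437309472676,0.002493014098340561,4
MEGATRON_12,3.5,very_stiff,3.2305002835123133,0.011868615401088191,4
MEGATRON_12,4.5,heterogeneous,4.102530979837369,0.01596169186438438,4
MEGATRON_12,4.5,neutral,4.073838453495431,0.018647446067267166,4
MEGATRON_12,4.5,soft,4.170683535301521,0.016894029709267937,4
MEGATRON_12,4.5,stiff,3.9307859891782684,0.021048365379008654,4
MEGATRON_12,4.5,very_soft,4.25798557024026,0.01489684555633214,4
MEGATRON_12,4.5,very_stiff,3.7976571881990253,0.02188039441981927,4
MEGATRON_12,5,heterogeneous,4.403420815913867,0.019454848061557162,4
MEGATRON_12,5,neutral,4.344485855440272,0.02447427123627664,4
MEGATRON_12,5,soft,4.473480050557362,0.02278130750841924,4
MEGATRON_12,5,stiff,4.15700575731897,0.025840072551808584,4
MEGATRON_12,5,very_soft,4.5738983340898915,0.02085549565536746,4
MEGATRON_12,5,very_stiff,4.001983269221796,0.023905581703327416,4
MEGATRON_9,3.5,heterogeneous,3.26807268172474,0.010166250382728158,4
MEGATRON_9,3.5,neutral,3.2659438918839383,0.010610116035419424,4
MEGATRON_9,3.5,soft,3.2953083435598787,0.006374258406295087,4
MEGATRON_9,3.5,stiff,3.2185286606618306,0.011589195430839118,4
MEGATRON_9,3.5,very_soft,3.315860253933689,0.0038818263075388174,4
MEGATRON_9,3.5,very_stiff,3.1772172523855495,0.013629671787959747,4
MEGATRON_9,4.5,heterogeneous,4.007620899408733,0.014763574366963376,4
MEGATRON_9,4.5,neutral,3.9763612999297,0.02005692504622901,4
MEGATRON_9,4.5,soft,4.069781318896781,0.018363141551825796,4
MEGATRON_9,4.5,stiff,3.837097302586251,0.021064669068945913,4
MEGATRON_9,4.5,very_soft,4.161073438356338,0.017772079002155668,4
MEGATRON_9,4.5,very_stiff,3.709327049989816,0.0226102061435199,4
MEGATRON_9,5,heterogeneous,4.279064248532118,0.018576838958623006,4
MEGATRON_9,5,neutral,4.214388942418731,0.02593104085122278,4
MEGATRON_9,5,soft,4.341714296701943,0.024023677452817985,4
MEGATRON_9,5,stiff,4.0348894589154485,0.027421116600800863,4
MEGATRON_9,5,very_soft,4.4539786667018815,0.022669175966101,4
MEGATRON_9,5,very_stiff,3.8790391625671097,0.025807322472628288,4
SYNERGY,3.5,heterogeneous,3.246127865535266,0.00805884058667662,4
SYNERGY,3.5,neutral,3.2442720887487235,0.008421588787150991,4
SYNERGY,3.5,soft,3.2708089428517324,0.006173161995085803,4
SYNERGY,3.5,stiff,3.2012758945788997,0.011093178162371275,4
SYNERGY,3.5,very_soft,3.2916550802034705,0.0036928069407361716,4
SYNERGY,3.5,very_stiff,3.163605332054371,0.011977245538938773,4
SYNERGY,4.5,heterogeneous,3.9975911164051032,0.015698937834970197,4
SYNERGY,4.5,neutral,3.951828868924123,0.01710597179196555,4
SYNERGY,4.5,soft,4.045472954007359,0.01698168243717752,4
SYNERGY,4.5,stiff,3.823006161145328,0.018544795993824626,4
SYNERGY,4.5,very_soft,4.133635955464169,0.014823195283910509,4
SYNERGY,4.5,very_stiff,3.7006964850430935,0.020593515894031668,4
SYNERGY,5,heterogeneous,4.2638878880239774,0.017770811283460336,4
SYNERGY,5,neutral,4.190210291416433,0.02281165981316301,4
SYNERGY,5,soft,4.310988148579735,0.021166467817860093,4
SYNERGY,5,stiff,4.015740439987327,0.0235644702276126,4
SYNERGY,5,very_soft,4.419538520632252,0.020169031313815342,4
SYNERGY,5,very_stiff,3.862429686684599,0.02390203243515896,4
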