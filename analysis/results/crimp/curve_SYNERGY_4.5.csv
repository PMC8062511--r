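outer_diameter_mm,radial_force_N,design,diameter
4.213423642552744,9.052239884184592e-15,SYNERGY,4.5
4.206840190984053,0.14955479552137252,SYNERGY,4.5
4.200256739415363,0.2988732796186322,SYNERGY,4.5
4.193673287846672,0.4479565755080382,SYNERGY,4.5
4.187089836277981,0.5968058005015404,SYNERGY,4.5
4.180506384709291,0.7454220660496629,SYNERGY,4.5
4.1739229331406005,0.8938064777840098,SYNERGY,4.5
4.16733948157191,1.041960135559296,SYNERGY,4.5
4.16075603000322,1.1898841334950752,SYNERGY,4.5
4.154172578434529,1.3375795600172293,SYNERGY,4.5
4.147589126865839,1.4850474978988588,SYNERGY,4.5
4.141005675297148,1.6322890243010666,SYNERGY,4.5
4.134422223728457,1.7793052108131997,SYNERGY,4.5
4.127838772159767,1.9260971234928381,SYNERGY,4.5
4.121255320591076,2.0726658229055768,SYNERGY,4.5
4.114671869022385,2.2190123641641395,SYNERGY,4.5
4.108088417453695,2.365137796967418,SYNERGY,4.5
4.101504965885004,2.511043165639236,SYNERGY,4.5
4.094921514316313,2.6567295091664618,SYNERGY,4.5
4.088338062747623,2.802197861237147,SYNERGY,4.5
4.0817546111789325,2.9474492502781735,SYNERGY,4.5
4.075171159610242,3.092484699492589,SYNERGY,4.5
4.068587708041552,3.237305226896609,SYNERGY,4.5
4.062004256472861,3.381911845356504,SYNERGY,4.5
4.05542080490417,3.5263055626247795,SYNERGY,4.5
4.04883735333548,3.6704873813765433,SYNERGY,4.5
4.042253901766789,3.8144582992451657,SYNERGY,4.5
4.035670450198098,3.9582193088578577,SYNERGY,4.5
4.029086998629408,4.101771397870903,SYNERGY,4.5
4.022503547060717,4.245115549004602,SYNERGY,4.5
4.015920095492026,4.3882527400778395,SYNERGY,4.5
4.009336643923336,4.531183944042516,SYNERGY,4.5
4.002753192354645,4.673910129017631,SYNERGY,4.5
3.9961697407859544,4.816432258323012,SYNERGY,4.5
3.989586289217264,4.958751290512907,SYNERGY,4.5
3.9830028376485735,5.100868179409069,SYNERGY,4.5
3.976419386079883,5.242783874133987,SYNERGY,4.5
3.969835934511192,5.384499319143305,SYNERGY,4.5
3.9632524829425018,5.526015454258424,SYNERGY,4.5
3.9566690313738113,5.667333214698616,SYNERGY,4.5
3.9500855798051204,5.808453531112926,SYNERGY,4.5
3.94350212823643,5.949377329611734,SYNERGY,4.5
3.9369186766677395,6.090105531798307,SYNERGY,4.5
3.930335225099049,6.230639054799824,SYNERGY,4.5
3.923751773530358,6.370978811298208,SYNERGY,4.5
3.9171683219616678,6.447979740328866,SYNERGY,4.5
3.9105848703929773,6.445868077910168,SYNERGY,4.5
3.9040014188242864,6.443764562351402,SYNERGY,4.5
3.897417967255596,6.44166916787219,SYNERGY,4.5
3.8908345156869055,6.439581868834925,SYNERGY,4.5
3.884251064118215,6.43750263974386,SYNERGY,4.5
3.877667612549524,6.435431455244183,SYNERGY,4.5
3.8710841609808337,6.4333682901211064,SYNERGY,4.5
3.8645007094121433,6.431313119298952,SYNERGY,4.5
3.8579172578434524,6.429265917840271,SYNERGY,4.5
3.851333806274762,6.427226660944946,SYNERGY,4.5
3.8447503547060715,6.425195323949309,SYNERGY,4.5
3.8381669031373806,6.423171882325259,SYNERGY,4.5
3.83158345156869,6.421156311679409,SYNERGY,4.5
3.8249999999999997,6.419148587752218,SYNERGY,4.5
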