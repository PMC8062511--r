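outer_diameter_mm,radial_force_N,design,diameter
3.221366332791877,-0,MEGATRON_9,3.5
3.2171906322360826,0.1041321043961227,MEGATRON_9,3.5
3.213014931680288,0.2081877425107442,MEGATRON_9,3.5
3.2088392311244935,0.3121671438517609,MEGATRON_9,3.5
3.204663530568699,0.4160705373105717,MEGATRON_9,3.5
3.2004878300129045,0.5198981511644576,MEGATRON_9,3.5
3.1963121294571097,0.6236502130792642,MEGATRON_9,3.5
3.1921364289013154,0.7273269501118808,MEGATRON_9,3.5
3.1879607283455207,0.8309285887127301,MEGATRON_9,3.5
3.1837850277897264,0.9344553547282682,MEGATRON_9,3.5
3.1796093272339316,1.037907473403582,MEGATRON_9,3.5
3.1754336266781373,1.141285169384668,MEGATRON_9,3.5
3.1712579261223426,1.244588666721132,MEGATRON_9,3.5
3.1670822255665483,1.3478181888684244,MEGATRON_9,3.5
3.1629065250107535,1.4509739586904995,MEGATRON_9,3.5
3.1587308244549592,1.554056198462034,MEGATRON_9,3.5
3.1545551238991645,1.6570651298710524,MEGATRON_9,3.5
3.15037942334337,1.7600009740211648,MEGATRON_9,3.5
3.1462037227875754,1.8628639514341088,MEGATRON_9,3.5
3.142028022231781,1.9656542820520504,MEGATRON_9,3.5
3.1378523216759864,2.068372185239977,MEGATRON_9,3.5
3.133676621120192,2.171017879788105,MEGATRON_9,3.5
3.1295009205643973,2.273591583914216,MEGATRON_9,3.5
3.125325220008603,2.376093515265959,MEGATRON_9,3.5
3.1211495194528083,2.478523890923224,MEGATRON_9,3.5
3.116973818897014,2.580882927400532,MEGATRON_9,3.5
3.1127981183412192,2.683170840649223,MEGATRON_9,3.5
3.108622417785425,2.785387846059817,MEGATRON_9,3.5
3.10444671722963,2.8875341584643857,MEGATRON_9,3.5
3.100271016673836,2.989609992138646,MEGATRON_9,3.5
3.096095316118041,3.0916155608044718,MEGATRON_9,3.5
3.091919615562247,3.1935510776319274,MEGATRON_9,3.5
3.087743915006452,3.295416755241722,MEGATRON_9,3.5
3.0835682144506578,3.397212805707245,MEGATRON_9,3.5
3.079392513894863,3.4989394405570353,MEGATRON_9,3.5
3.0752168133390687,3.6005968707767497,MEGATRON_9,3.5
3.071041112783274,3.702185306811613,MEGATRON_9,3.5
3.0668654122274797,3.8037049585683995,MEGATRON_9,3.5
3.062689711671685,3.9051560354178254,MEGATRON_9,3.5
3.0585140111158906,4.006538746196591,MEGATRON_9,3.5
3.054338310560096,4.107853299209624,MEGATRON_9,3.5
3.0501626100043016,4.209099902232211,MEGATRON_9,3.5
3.045986909448507,4.310278762512111,MEGATRON_9,3.5
3.0418112088927125,4.411390086771826,MEGATRON_9,3.5
3.0376355083369178,4.512434081210632,MEGATRON_9,3.5
3.0334598077811235,4.61341095150667,MEGATRON_9,3.5
3.0292841072253287,4.714320902819204,MEGATRON_9,3.5
3.0251084066695344,4.815164139790547,MEGATRON_9,3.5
3.0209327061137397,4.915940866548354,MEGATRON_9,3.5
3.0167570055579453,5.016651286707511,MEGATRON_9,3.5
3.0125813050021506,5.117295603372346,MEGATRON_9,3.5
3.0084056044463563,5.217874019138659,MEGATRON_9,3.5
3.0042299038905615,5.318386736095805,MEGATRON_9,3.5
3.0000542033347672,5.418833955828634,MEGATRON_9,3.5
2.9958785027789725,5.519215879419717,MEGATRON_9,3.5
2.991702802223178,5.619532707451196,MEGATRON_9,3.5
2.9875271016673834,5.719784640006939,MEGATRON_9,3.5
2.983351401111589,5.819971876674477,MEGATRON_9,3.5
2.9791757005557944,5.920094616547077,MEGATRON_9,3.5
2.975,6.0201530582256355,MEGATRON_9,3.5
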