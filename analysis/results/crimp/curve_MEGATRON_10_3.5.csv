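outer_diameter_mm,radial_force_N,design,diameter
3.264318895102001,-0,MEGATRON_10,3.5
3.259415185015526,0.19741127533732364,MEGATRON_10,3.5
3.2545114749290516,0.39463519808282305,MEGATRON_10,3.5
3.249607764842577,0.5916724502789199,MEGATRON_10,3.5
3.2447040547561024,0.7885237116397251,MEGATRON_10,3.5
3.2398003446696277,0.9851896595629956,MEGATRON_10,3.5
3.234896634583153,1.1816709691419027,MEGATRON_10,3.5
3.2299929244966785,1.3779683131768643,MEGATRON_10,3.5
3.225089214410204,1.57408236218727,MEGATRON_10,3.5
3.2201855043237293,1.7700137844230621,MEGATRON_10,3.5
3.215281794237255,1.9657632458763732,MEGATRON_10,3.5
3.2103780841507805,2.1613314102930183,MEGATRON_10,3.5
3.205474374064306,2.356718939183929,MEGATRON_10,3.5
3.2005706639778313,2.5519264918364843,MEGATRON_10,3.5
3.1956669538913567,2.7469547253259354,MEGATRON_10,3.5
3.190763243804882,2.9418042945265555,MEGATRON_10,3.5
3.1858595337184075,3.1364758521228064,MEGATRON_10,3.5
3.180955823631933,3.3309700486205607,MEGATRON_10,3.5
3.1760521135454582,3.525287532358029,MEGATRON_10,3.5
3.1711484034589836,3.7194289495168373,MEGATRON_10,3.5
3.166244693372509,3.9133949441329055,MEGATRON_10,3.5
3.1613409832860344,4.107186158107354,MEGATRON_10,3.5
3.15643727319956,4.300803231217222,MEGATRON_10,3.5
3.151533563113085,4.494246801126338,MEGATRON_10,3.5
3.1466298530266106,4.68751750339587,MEGATRON_10,3.5
3.141726142940136,4.880615971494961,MEGATRON_10,3.5
3.1368224328536614,5.073542836811413,MEGATRON_10,3.5
3.1319187227671867,5.266298728661999,MEGATRON_10,3.5
3.127015012680712,5.458884274303033,MEGATRON_10,3.5
3.1221113025942375,5.651300098940691,MEGATRON_10,3.5
3.117207592507763,5.843546825741339,MEGATRON_10,3.5
3.1123038824212887,6.0356250758418,MEGATRON_10,3.5
3.107400172334814,6.227535468359571,MEGATRON_10,3.5
3.1024964622483395,6.419278620402969,MEGATRON_10,3.5
3.097592752161865,6.6108551470811054,MEGATRON_10,3.5
3.0926890420753903,6.802265661514098,MEGATRON_10,3.5
3.0877853319889157,6.993510774842996,MEGATRON_10,3.5
3.082881621902441,7.184591096239546,MEGATRON_10,3.5
3.0779779118159665,7.375507232916265,MEGATRON_10,3.5
3.073074201729492,7.566259790136127,MEGATRON_10,3.5
3.0681704916430173,7.756849371222363,MEGATRON_10,3.5
3.0632667815565426,7.947276577568097,MEGATRON_10,3.5
3.058363071470068,8.13754200864611,MEGATRON_10,3.5
3.0534593613835934,8.327646262018318,MEGATRON_10,3.5
3.048555651297119,8.517589933345306,MEGATRON_10,3.5
3.043651941210644,8.707373616395971,MEGATRON_10,3.5
3.0387482311241696,8.896997903056736,MEGATRON_10,3.5
3.033844521037695,9.086463383341078,MEGATRON_10,3.5
3.0289408109512204,9.275770645398794,MEGATRON_10,3.5
3.024037100864746,9.42804402901545,MEGATRON_10,3.5
3.0191333907782716,9.426581888472107,MEGATRON_10,3.5
3.014229680691797,9.425125475157362,MEGATRON_10,3.5
3.0093259706053224,9.423674778180473,MEGATRON_10,3.5
3.0044222605188478,9.422229786696716,MEGATRON_10,3.5
2.999518550432373,9.42079048990721,MEGATRON_10,3.5
2.9946148403458985,9.419356877058684,MEGATRON_10,3.5
2.989711130259424,9.417928937443302,MEGATRON_10,3.5
2.9848074201729493,9.416506660398458,MEGATRON_10,3.5
2.9799037100864747,9.415090035306587,MEGATRON_10,3.5
2.975,9.413679051594965,MEGATRON_10,3.5
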