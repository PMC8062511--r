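outer_diameter_mm,radial_force_N,design,diameter
4.79299304990608,-0,MEGATRON_12,5
4.783789777873774,0.5965810723334346,MEGATRON_12,5
4.774586505841468,1.1914225058077421,MEGATRON_12,5
4.765383233809161,1.7845372638873584,MEGATRON_12,5
4.756179961776854,2.3759381927732437,MEGATRON_12,5
4.746976689744548,2.9656380228089607,MEGATRON_12,5
4.7377734177122415,3.5536493698690372,MEGATRON_12,5
4.728570145679935,4.1399847367242,MEGATRON_12,5
4.719366873647629,4.724656514389871,MEGATRON_12,5
4.7101636016153225,5.307676983453064,MEGATRON_12,5
4.700960329583015,5.889058315381819,MEGATRON_12,5
4.691757057550709,6.4688125738147315,MEGATRON_12,5
4.682553785518403,7.046951715833297,MEGATRON_12,5
4.673350513486096,7.623487593215178,MEGATRON_12,5
4.66414724145379,8.19843195367038,MEGATRON_12,5
4.654943969421484,8.771796442059342,MEGATRON_12,5
4.6457406973891775,9.343592601594882,MEGATRON_12,5
4.63653742535687,9.913831875025874,MEGATRON_12,5
4.627334153324564,10.482525605805472,MEGATRON_12,5
4.618130881292258,11.049685039242434,MEGATRON_12,5
4.608927609259951,11.61532132363678,MEGATRON_12,5
4.599724337227645,12.179445511398862,MEGATRON_12,5
4.590521065195339,12.742068560153996,MEGATRON_12,5
4.5813177931630324,13.30252186823673,MEGATRON_12,5
4.572114521130725,13.294287066285888,MEGATRON_12,5
4.562911249098419,13.286098536848218,MEGATRON_12,5
4.553707977066113,13.277956014871217,MEGATRON_12,5
4.544504705033806,13.269859237698101,MEGATRON_12,5
4.5353014330015,13.261807945041134,MEGATRON_12,5
4.526098160969194,13.253801878955343,MEGATRON_12,5
4.5168948889368865,13.24584078381256,MEGATRON_12,5
4.50769161690458,13.237924406275837,MEGATRON_12,5
4.498488344872274,13.230052495274228,MEGATRON_12,5
4.489285072839968,13.222224801977879,MEGATRON_12,5
4.480081800807661,13.214441079773463,MEGATRON_12,5
4.470878528775355,13.206701084239983,MEGATRON_12,5
4.461675256743048,13.199004573124832,MEGATRON_12,5
4.4524719847107415,13.191351306320252,MEGATRON_12,5
4.443268712678435,13.18374104584005,MEGATRON_12,5
4.434065440646129,13.176173555796662,MEGATRON_12,5
4.4248621686138225,13.168648602378502,MEGATRON_12,5
4.415658896581516,13.161165953827616,MEGATRON_12,5
4.40645562454921,13.153725380417647,MEGATRON_12,5
4.397252352516903,13.146326654432071,MEGATRON_12,5
4.388049080484596,13.138969550142756,MEGATRON_12,5
4.37884580845229,13.131653843788746,MEGATRON_12,5
4.369642536419984,13.12437931355537,MEGATRON_12,5
4.3604392643876775,13.117145739553646,MEGATRON_12,5
4.351235992355371,13.109952903799872,MEGATRON_12,5
4.342032720323065,13.102800590195573,MEGATRON_12,5
4.332829448290758,13.095688584507656,MEGATRON_12,5
4.323626176258451,13.088616674348836,MEGATRON_12,5
4.314422904226145,13.081584649158337,MEGATRON_12,5
4.305219632193839,13.07459230018279,MEGATRON_12,5
4.296016360161532,13.067639420457459,MEGATRON_12,5
4.286813088129226,13.06072580478763,MEGATRON_12,5
4.27760981609692,13.053851249730279,MEGATRON_12,5
4.268406544064613,13.04701555357599,MEGATRON_12,5
4.259203272032306,13.040218516331047,MEGATRON_12,5
4.25,13.033459939699828,MEGATRON_12,5
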