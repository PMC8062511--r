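outer_diameter_mm,radial_force_N,design,diameter
4.787468147753461,0,MEGATRON_10,5
4.778358518130521,0.48476343813733624,MEGATRON_10,5
4.7692488885075806,0.9678588877101539,MEGATRON_10,5
4.7601392588846405,1.4493001876537972,MEGATRON_10,5
4.7510296292617005,1.929101033405154,MEGATRON_10,5
4.74191999963876,2.4072749788556425,MEGATRON_10,5
4.73281037001582,2.883835438272284,MEGATRON_10,5
4.72370074039288,3.358795688186799,MEGATRON_10,5
4.71459111076994,3.8321688692541036,MEGATRON_10,5
4.705481481147,4.3039679880807915,MEGATRON_10,5
4.69637185152406,4.774205919022917,MEGATRON_10,5
4.68726222190112,5.242895405955862,MEGATRON_10,5
4.67815259227818,5.71004906401443,MEGATRON_10,5
4.66904296265524,6.1756793813056365,MEGATRON_10,5
4.6599333330323,6.639798720593651,MEGATRON_10,5
4.65082370340936,7.102419320957798,MEGATRON_10,5
4.641714073786421,7.563553299424001,MEGATRON_10,5
4.632604444163481,8.023212652570567,MEGATRON_10,5
4.623494814540541,8.481409258107725,MEGATRON_10,5
4.614385184917601,8.938154876432854,MEGATRON_10,5
4.605275555294661,9.393461152160883,MEGATRON_10,5
4.596165925671721,9.847339615630482,MEGATRON_10,5
4.587056296048781,10.299801684386692,MEGATRON_10,5
4.577946666425841,10.750858664640589,MEGATRON_10,5
4.5688370368029005,11.189821536522956,MEGATRON_10,5
4.5597274071799605,11.181092829765163,MEGATRON_10,5
4.5506177775570205,11.172414971871257,MEGATRON_10,5
4.54150814793408,11.163787626358145,MEGATRON_10,5
4.53239851831114,11.155210460131434,MEGATRON_10,5
4.5232888886882,11.146683143442818,MEGATRON_10,5
4.51417925906526,11.138205349848183,MEGATRON_10,5
4.50506962944232,11.129776756166287,MEGATRON_10,5
4.49595999981938,11.12139704243814,MEGATRON_10,5
4.48685037019644,11.113065891886954,MEGATRON_10,5
4.4777407405735,11.104782990878723,MEGATRON_10,5
4.46863111095056,11.096548028883413,MEGATRON_10,5
4.45952148132762,11.088360698436713,MEGATRON_10,5
4.45041185170468,11.08022069510239,MEGATRON_10,5
4.44130222208174,11.072127717435203,MEGATRON_10,5
4.4321925924588,11.064081466944359,MEGATRON_10,5
4.42308296283586,11.056081648057535,MEGATRON_10,5
4.41397333321292,11.048127968085454,MEGATRON_10,5
4.40486370358998,11.04022013718693,MEGATRON_10,5
4.39575407396704,11.032357868334504,MEGATRON_10,5
4.3866444443441,11.02454087728054,MEGATRON_10,5
4.377534814721161,11.016768882523849,MEGATRON_10,5
4.36842518509822,11.009041605276781,MEGATRON_10,5
4.3593155554752805,11.00135876943284,MEGATRON_10,5
4.3502059258523404,10.993720101534727,MEGATRON_10,5
4.3410962962294,10.986125330742883,MEGATRON_10,5
4.33198666660646,10.978574188804501,MEGATRON_10,5
4.32287703698352,10.971066410022932,MEGATRON_10,5
4.31376740736058,10.963601731227612,MEGATRON_10,5
4.30465777773764,10.956179891744377,MEGATRON_10,5
4.2955481481147,10.948800633366197,MEGATRON_10,5
4.28643851849176,10.941463700324375,MEGATRON_10,5
4.27732888886882,10.934168839260137,MEGATRON_10,5
4.26821925924588,10.92691579919662,MEGATRON_10,5
4.25910962962294,10.919704331511262,MEGATRON_10,5
4.25,10.912534189908628,MEGATRON_10,5
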