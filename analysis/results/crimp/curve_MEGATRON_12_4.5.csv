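outer_diameter_mm,radial_force_N,design,diameter
4.28558651629065,2.2840884303129372e-14,MEGATRON_12,4.5
4.277779965167079,0.4594088863375217,MEGATRON_12,4.5
4.269973414043509,0.9178967537517431,MEGATRON_12,4.5
4.262166862919939,1.3754689570396519,MEGATRON_12,4.5
4.254360311796368,1.8321308158041103,MEGATRON_12,4.5
4.246553760672798,2.2878876147700895,MEGATRON_12,4.5
4.238747209549228,2.7427446040972914,MEGATRON_12,4.5
4.2309406584256575,3.1967069996895288,MEGATRON_12,4.5
4.223134107302087,3.6497799835005535,MEGATRON_12,4.5
4.215327556178517,4.10196870383695,MEGATRON_12,4.5
4.2075210050549465,4.553278275657407,MEGATRON_12,4.5
4.199714453931376,5.003713780869411,MEGATRON_12,4.5
4.191907902807806,5.453280268622208,MEGATRON_12,4.5
4.184101351684236,5.901982755597024,MEGATRON_12,4.5
4.176294800560665,6.3498262262938745,MEGATRON_12,4.5
4.168488249437095,6.796815633315991,MEGATRON_12,4.5
4.160681698313525,7.242955897650561,MEGATRON_12,4.5
4.152875147189954,7.6882519089471115,MEGATRON_12,4.5
4.145068596066384,8.13270852579231,MEGATRON_12,4.5
4.137262044942814,8.5763305759827,MEGATRON_12,4.5
4.129455493819243,9.01912285679406,MEGATRON_12,4.5
4.121648942695673,9.461090135247916,MEGATRON_12,4.5
4.113842391572103,9.902237148375749,MEGATRON_12,4.5
4.106035840448532,10.342568603479988,MEGATRON_12,4.5
4.098229289324962,10.78208917839268,MEGATRON_12,4.5
4.090422738201392,11.220803521731108,MEGATRON_12,4.5
4.082616187077821,11.658716253151232,MEGATRON_12,4.5
4.07480963595425,12.095831963598055,MEGATRON_12,4.5
4.06700308483068,12.524259827165427,MEGATRON_12,4.5
4.05919653370711,12.519404397692101,MEGATRON_12,4.5
4.051389982583539,12.514572929278218,MEGATRON_12,4.5
4.043583431459969,12.509765325612682,MEGATRON_12,4.5
4.035776880336399,12.504981491052472,MEGATRON_12,4.5
4.027970329212828,12.500221330617185,MEGATRON_12,4.5
4.020163778089258,12.495484749983587,MEGATRON_12,4.5
4.012357226965688,12.490771655480245,MEGATRON_12,4.5
4.004550675842117,12.486081954082206,MEGATRON_12,4.5
3.996744124718547,12.481415553405737,MEGATRON_12,4.5
3.988937573594977,12.476772361703102,MEGATRON_12,4.5
3.9811310224714065,12.472152287857423,MEGATRON_12,4.5
3.973324471347836,12.467555241377564,MEGATRON_12,4.5
3.965517920224266,12.462981132393073,MEGATRON_12,4.5
3.9577113691006955,12.458429871649196,MEGATRON_12,4.5
3.9499048179771252,12.453901370501898,MEGATRON_12,4.5
3.9420982668535545,12.449395540912993,MEGATRON_12,4.5
3.934291715729984,12.44491229544528,MEGATRON_12,4.5
3.926485164606414,12.440451547257725,MEGATRON_12,4.5
3.9186786134828435,12.436013210100729,MEGATRON_12,4.5
3.910872062359273,12.43159719831141,MEGATRON_12,4.5
3.903065511235703,12.42720342680894,MEGATRON_12,4.5
3.8952589601121326,12.422831811089935,MEGATRON_12,4.5
3.8874524089885623,12.418482267223894,MEGATRON_12,4.5
3.879645857864992,12.414154711848667,MEGATRON_12,4.5
3.8718393067414216,12.40984906216599,MEGATRON_12,4.5
3.8640327556178513,12.405565235937035,MEGATRON_12,4.5
3.856226204494281,12.401303151478041,MEGATRON_12,4.5
3.8484196533707107,12.397062727655957,MEGATRON_12,4.5
3.8406131022471404,12.392843883884153,MEGATRON_12,4.5
3.83280655112357,12.388646540118135,MEGATRON_12,4.5
3.8249999999999997,12.384470616851356,MEGATRON_12,4.5
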