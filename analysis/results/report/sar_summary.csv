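design,diameter,plaque,mean,sem,n
MEGATRON_10,3.5,heterogeneous,14.107338990259912,0.08076558923878707,4
MEGATRON_10,3.5,neutral,14.108591599806193,0.0812727942312371,4
MEGATRON_10,3.5,soft,14.006751132965622,0.06984318135833026,4
MEGATRON_10,3.5,stiff,14.27794222510735,0.09073307022648201,4
MEGATRON_10,3.5,very_soft,13.947723461943587,0.06187424912623518,4
MEGATRON_10,3.5,very_stiff,14.448070971902016,0.10137138435346167,4
MEGATRON_10,4.5,heterogeneous,12.903434026987714,0.04298644090042082,4
MEGATRON_10,4.5,neutral,12.950305871382119,0.050342593455990285,4
MEGATRON_10,4.5,soft,12.721825074506192,0.04424216849189515,4
MEGATRON_10,4.5,stiff,13.304394593824956,0.058081010857573154,4
MEGATRON_10,4.5,very_soft,12.52263759490426,0.03942271308671347,4
MEGATRON_10,4.5,very_stiff,13.677671759460146,0.06427209240375424,4
MEGATRON_10,5,heterogeneous,12.558337795772744,0.04798326687528572,4
MEGATRON_10,5,neutral,12.6398519796357,0.05555104983304061,4
MEGATRON_10,5,soft,12.378879798826635,0.050091527454288944,4
MEGATRON_10,5,stiff,13.042570141730444,0.0631161190906874,4
MEGATRON_10,5,very_soft,12.158433765223833,0.04441850047255804,4
MEGATRON_10,5,very_stiff,13.456522694419563,0.06522593575419651,4
MEGATRON_12,3.5,heterogeneous,16.509147015213255,0.0899841608480005,4
MEGATRON_12,3.5,neutral,16.51450794557691,0.09108625489666361,4
MEGATRON_12,3.5,soft,16.40032428516279,0.07730934003881502,4
MEGATRON_12,3.5,stiff,16.738921952018927,0.10318779049680238,4
MEGATRON_12,3.5,very_soft,16.333576749722702,0.06796817374480266,4
MEGATRON_12,3.5,very_stiff,16.95743714013608,0.11502328756754363,4
MEGATRON_12,4.5,heterogeneous,14.928173942416372,0.053801576539182425,4
MEGATRON_12,4.5,neutral,14.995477115098483,0.05976375285876398,4
MEGATRON_12,4.5,soft,14.706346300846558,0.0518788681308165,4
MEGATRON_12,4.5,stiff,15.440995328301986,0.07194856226945585,4
MEGATRON_12,4.5,very_soft,14.455815397067475,0.043146911359168295,4
MEGATRON_12,4.5,very_stiff,15.91314944233806,0.08122201397402229,4
MEGATRON_12,5,heterogeneous,14.431787732299771,0.056035866916948375,4
MEGATRON_12,5,neutral,14.543677782431658,0.06808523484555899,4
MEGATRON_12,5,soft,14.211416166311109,0.05910031337606197,4
MEGATRON_12,5,stiff,15.06144173926196,0.07943144995693632,4
MEGATRON_12,5,very_soft,13.947813381228414,0.05135029841514993,4
MEGATRON_12,5,very_stiff,15.591568761394779,0.08276822863161304,4
MEGATRON_9,3.5,heterogeneous,13.23328189876901,0.08427851361239208,4
MEGATRON_9,3.5,neutral,13.239372599625884,0.08700732242296239,4
MEGATRON_9,3.5,soft,13.14116799388315,0.07286808475281843,4
MEGATRON_9,3.5,stiff,13.40333672353168,0.09400105132137836,4
MEGATRON_9,3.5,very_soft,13.075649720329453,0.0645158721533173,4
MEGATRON_9,3.5,very_stiff,13.553376920731308,0.10505023306692095,4
MEGATRON_9,4.5,heterogeneous,12.151347532019358,0.044280290425627505,4
MEGATRON_9,4.5,neutral,12.21016938981464,0.054411769937681424,4
MEGATRON_9,4.5,soft,11.98113394562001,0.04854939762820663,4
MEGATRON_9,4.5,stiff,12.562052413095216,0.06136486242341129,4
MEGATRON_9,4.5,very_soft,11.765147516219912,0.04336284629185179,4
MEGATRON_9,4.5,very_stiff,12.931939333764905,0.07018108803398365,4
MEGATRON_9,5,heterogeneous,11.819666602071116,0.04762866192533706,4
MEGATRON_9,5,neutral,11.92069461081439,0.06052324890413772,4
MEGATRON_9,5,soft,11.650185592670857,0.054586031014526165,4
MEGATRON_9,5,stiff,12.32922891455572,0.06939678219480862,4
MEGATRON_9,5,very_soft,11.414722757351525,0.04805777418060034,4
MEGATRON_9,5,very_stiff,12.755299807527996,0.07373634149452465,4
SYNERGY,3.5,heterogeneous,13.068625358155035,0.07630328360300911,4
SYNERGY,3.5,neutral,13.073965353093309,0.07759850191082747,4
SYNERGY,3.5,soft,12.984897815306253,0.07005860696929286,4
SYNERGY,3.5,stiff,13.22230942868491,0.08827206947777992,4
SYNERGY,3.5,very_soft,12.917644435249965,0.062001221875951765,4
SYNERGY,3.5,very_stiff,13.358541893166255,0.09468148144187409,4
SYNERGY,4.5,heterogeneous,11.969497105862205,0.04417611291820444,4
SYNERGY,4.5,neutral,12.062269194941681,0.047758291683984946,4
SYNERGY,4.5,soft,11.831029224977565,0.04470642026474874,4
SYNERGY,4.5,stiff,12.396221500631988,0.05386695614720476,4
SYNERGY,4.5,very_soft,11.6187075541774,0.037536292725031596,4
SYNERGY,4.5,very_stiff,12.746276425589464,0.0625220964363108,4
SYNERGY,5,heterogeneous,11.58483076490992,0.04360506569120367,4
SYNERGY,5,neutral,11.711697164755854,0.05294329846901445,4
SYNERGY,5,soft,11.451227256626524,0.04742781899494189,4
SYNERGY,5,stiff,12.109978245918718,0.05933023657116133,4
SYNERGY,5,very_soft,11.217646025576133,0.0427416021262697,4
SYNERGY,5,very_stiff,12.52259273144443,0.06537700954537981,4
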