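outer_diameter_mm,radial_force_N,design,diameter
4.23622455557132,0,MEGATRON_9,4.5
4.229254647849772,0.20166783270617478,MEGATRON_9,4.5
4.222284740128224,0.40295641578044095,MEGATRON_9,4.5
4.215314832406676,0.6038677851533459,MEGATRON_9,4.5
4.208344924685129,0.8044039642785636,MEGATRON_9,4.5
4.20137501696358,1.004566964236767,MEGATRON_9,4.5
4.194405109242033,1.204358783838655,MEGATRON_9,4.5
4.187435201520485,1.4037814097269887,MEGATRON_9,4.5
4.180465293798937,1.6028368164775932,MEGATRON_9,4.5
4.17349538607739,1.8015269666992328,MEGATRON_9,4.5
4.166525478355842,1.9998538111326472,MEGATRON_9,4.5
4.159555570634294,2.1978192887485966,MEGATRON_9,4.5
4.152585662912746,2.3954253268447365,MEGATRON_9,4.5
4.145615755191199,2.5926738411419814,MEGATRON_9,4.5
4.13864584746965,2.78956673587945,MEGATRON_9,4.5
4.131675939748103,2.986105903908673,MEGATRON_9,4.5
4.124706032026555,3.1822932267869377,MEGATRON_9,4.5
4.117736124305007,3.378130574869712,MEGATRON_9,4.5
4.1107662165834595,3.5736198074020193,MEGATRON_9,4.5
4.103796308861912,3.7687627726090853,MEGATRON_9,4.5
4.096826401140364,3.963561307786095,MEGATRON_9,4.5
4.089856493418816,4.158017239386859,MEGATRON_9,4.5
4.082886585697268,4.352132383112046,MEGATRON_9,4.5
4.07591667797572,4.545908543996053,MEGATRON_9,4.5
4.068946770254173,4.73934751649352,MEGATRON_9,4.5
4.0619768625326245,4.93245108456464,MEGATRON_9,4.5
4.055006954811077,5.125221021759902,MEGATRON_9,4.5
4.0480370470895295,5.317659091303767,MEGATRON_9,4.5
4.041067139367981,5.509767046177932,MEGATRON_9,4.5
4.034097231646434,5.701546629203318,MEGATRON_9,4.5
4.027127323924886,5.892999573121672,MEGATRON_9,4.5
4.020157416203338,6.084127600676254,MEGATRON_9,4.5
4.01318750848179,6.2749324246916025,MEGATRON_9,4.5
4.006217600760243,6.46541574815283,MEGATRON_9,4.5
3.9992476930386944,6.655579264283998,MEGATRON_9,4.5
3.9922777853171465,6.845424656625714,MEGATRON_9,4.5
3.985307877595599,7.034953599112075,MEGATRON_9,4.5
3.978337969874051,7.224167756146963,MEGATRON_9,4.5
3.971368062152503,7.41306878267942,MEGATRON_9,4.5
3.9643981544309557,7.557465692759087,MEGATRON_9,4.5
3.9574282467094077,7.5544532781233515,MEGATRON_9,4.5
3.95045833898786,7.551453537208501,MEGATRON_9,4.5
3.9434884312663123,7.548466422541651,MEGATRON_9,4.5
3.9365185235447644,7.5454918869494385,MEGATRON_9,4.5
3.9295486158232165,7.542529883555766,MEGATRON_9,4.5
3.922578708101669,7.539580365779566,MEGATRON_9,4.5
3.915608800380121,7.536643287332588,MEGATRON_9,4.5
3.908638892658573,7.533718602217194,MEGATRON_9,4.5
3.9016689849370256,7.530806264724198,MEGATRON_9,4.5
3.8946990772154777,7.5279062294307,MEGATRON_9,4.5
3.8877291694939298,7.525018451197959,MEGATRON_9,4.5
3.880759261772382,7.522142885169277,MEGATRON_9,4.5
3.8737893540508344,7.519279486767904,MEGATRON_9,4.5
3.8668194463292864,7.516428211694967,MEGATRON_9,4.5
3.8598495386077385,7.513589015927406,MEGATRON_9,4.5
3.852879630886191,7.510761855715948,MEGATRON_9,4.5
3.845909723164643,7.507946687583083,MEGATRON_9,4.5
3.838939815443095,7.505143468321068,MEGATRON_9,4.5
3.8319699077215477,7.50235215498994,MEGATRON_9,4.5
3.8249999999999997,7.499572704915561,MEGATRON_9,4.5
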