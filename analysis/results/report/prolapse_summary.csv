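design,diameter,plaque,mean,sem,n
MEGATRON_10,3.5,heterogeneous,0.07482379910784248,2.622520192304319e-7,4
MEGATRON_10,3.5,neutral,0.07482359797054161,4.6338932017479334e-7,4
MEGATRON_10,3.5,soft,0.07482379910784254,2.6225201924893565e-7,4
MEGATRON_10,3.5,stiff,0.0748227330366652,1.3283231965847502e-6,4
MEGATRON_10,3.5,very_soft,0.07482388382557592,1.7753428586490355e-7,4
MEGATRON_10,3.5,very_stiff,0.0747490722452161,1.3493516668801958e-5,4
MEGATRON_10,4.5,heterogeneous,0.08411284786046858,5.455997489805435e-5,4
MEGATRON_10,4.5,neutral,0.08411284786046858,5.455997489805435e-5,4
MEGATRON_10,4.5,soft,0.08413221353736411,5.1539163585981616e-5,4
MEGATRON_10,4.5,stiff,0.08395650284571776,7.395079183463559e-5,4
MEGATRON_10,4.5,very_soft,0.08413957798058591,5.0373177980006066e-5,4
MEGATRON_10,4.5,very_stiff,0.08291341521979712,7.153167838487935e-5,4
MEGATRON_10,5,heterogeneous,0.08268957779482211,1.596884970855872e-4,4
MEGATRON_10,5,neutral,0.08273951189392725,1.5712960742327996e-4,4
MEGATRON_10,5,soft,0.08277464930920808,1.5276359373349335e-4,4
MEGATRON_10,5,stiff,0.08236592286178734,1.8861970563430165e-4,4
MEGATRON_10,5,very_soft,0.08305141076653966,1.597816546204445e-4,4
MEGATRON_10,5,very_stiff,0.08040905381205288,2.1681929496303822e-4,4
MEGATRON_12,3.5,heterogeneous,0.05351209527468398,1.6947865636713042e-6,4
MEGATRON_12,3.5,neutral,0.05351209527468398,1.6947865636713042e-6,4
MEGATRON_12,3.5,soft,0.05351284859026084,9.414717028489178e-7,4
MEGATRON_12,3.5,stiff,0.05350893684047525,4.853220190015149e-6,4
MEGATRON_12,3.5,very_soft,0.053513167418386964,6.226444016094125e-7,4
MEGATRON_12,3.5,very_stiff,0.05347095045975164,1.225490434620491e-5,4
MEGATRON_12,4.5,heterogeneous,0.062335837833152885,2.7464902277359465e-5,4
MEGATRON_12,4.5,neutral,0.062335837833152885,2.7464902277359465e-5,4
MEGATRON_12,4.5,soft,0.062346453746081054,2.746571462769677e-5,4
MEGATRON_12,4.5,stiff,0.062258951764295634,2.9346694996329526e-5,4
MEGATRON_12,4.5,very_soft,0.062350544600547786,2.7481480089493486e-5,4
MEGATRON_12,4.5,very_stiff,0.06170310060053974,2.9194445042287154e-5,4
MEGATRON_12,5,heterogeneous,0.06276625206701691,5.990420013323486e-5,4
MEGATRON_12,5,neutral,0.06276328210188475,6.000606837445934e-5,4
MEGATRON_12,5,soft,0.06278637317017244,5.969146417559356e-5,4
MEGATRON_12,5,stiff,0.06260503989474808,6.257582284366414e-5,4
MEGATRON_12,5,very_soft,0.06279521071873406,5.949777609894706e-5,4
MEGATRON_12,5,very_stiff,0.061629952154253154,6.142406307918248e-5,4
MEGATRON_9,3.5,heterogeneous,0.09140593122260832,1.150924933699112e-5,4
MEGATRON_9,3.5,neutral,0.09138909115563443,2.237306039698395e-5,4
MEGATRON_9,3.5,soft,0.09140593122260843,1.1509249336965047e-5,4
MEGATRON_9,3.5,stiff,0.09132650873599185,6.232017655290175e-5,4
MEGATRON_9,3.5,very_soft,0.09141337764709562,6.71292149361817e-6,4
MEGATRON_9,3.5,very_stiff,0.09111197268315213,1.5155777237816655e-4,4
MEGATRON_9,4.5,heterogeneous,0.10454932035295195,6.285242281860074e-5,4
MEGATRON_9,4.5,neutral,0.10454932035295195,6.285242281860074e-5,4
MEGATRON_9,4.5,soft,0.10456860390908629,6.281341491810505e-5,4
MEGATRON_9,4.5,stiff,0.10439729054512625,7.625992280666363e-5,4
MEGATRON_9,4.5,very_soft,0.10457601642415304,6.282159553099771e-5,4
MEGATRON_9,4.5,very_stiff,0.10314595169724938,7.079247793200233e-5,4
MEGATRON_9,5,heterogeneous,0.1040394410038219,1.5576391683020752e-4,4
MEGATRON_9,5,neutral,0.10404482994376252,1.5518571796606509e-4,4
MEGATRON_9,5,soft,0.10408823986914473,1.5503813289534244e-4,4
MEGATRON_9,5,stiff,0.10370425302777508,1.6652065148384173e-4,4
MEGATRON_9,5,very_soft,0.10410140696027137,1.5531937716389615e-4,4
MEGATRON_9,5,very_stiff,0.10179848633067645,1.3351546416490807e-4,4
SYNERGY,3.5,heterogeneous,0.07582329629837586,2.3727921583172634e-5,4
SYNERGY,3.5,neutral,0.07581303276508516,2.6866751075893977e-5,4
SYNERGY,3.5,soft,0.07583537819568648,1.3880486824844493e-5,4
SYNERGY,3.5,stiff,0.07574286416219567,6.761753522413919e-5,4
SYNERGY,3.5,very_soft,0.07584583282162816,7.802351510377435e-6,4
SYNERGY,3.5,very_stiff,0.07559645865499698,1.2646760021744056e-4,4
SYNERGY,4.5,heterogeneous,0.08892436354623234,5.172294424500653e-5,4
SYNERGY,4.5,neutral,0.08892436354623234,5.172294424500653e-5,4
SYNERGY,4.5,soft,0.08894052971386468,5.1700582412783355e-5,4
SYNERGY,4.5,stiff,0.08881177258010509,5.4585186785365915e-5,4
SYNERGY,4.5,very_soft,0.08894679133487182,5.170397412089948e-5,4
SYNERGY,4.5,very_stiff,0.08801862805651495,5.0383669419455925e-5,4
SYNERGY,5,heterogeneous,0.09010057196029597,8.235062200004801e-5,4
SYNERGY,5,neutral,0.09009350199590715,8.37819263824744e-5,4
SYNERGY,5,soft,0.09012485703960682,8.243833585284564e-5,4
SYNERGY,5,stiff,0.08988684610451692,9.450042469781322e-5,4
SYNERGY,5,very_soft,0.09013710893622995,8.191748157169139e-5,4
SYNERGY,5,very_stiff,0.08834046385620486,6.434017958627555e-5,4
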