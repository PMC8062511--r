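design,diameter,plaque,mean,sem,n
MEGATRON_10,3.5,heterogeneous,0.9997699298532625,0.002293415405457149,4
MEGATRON_10,3.5,neutral,0.9996549098762668,0.0023224838253215153,4
MEGATRON_10,3.5,soft,1.0085734362281409,0.0013474119885733362,4
MEGATRON_10,3.5,stiff,0.9849964443034611,0.0026984032126816685,4
MEGATRON_10,3.5,very_soft,1.013859165922704,7.15749521759357e-4,4
MEGATRON_10,3.5,very_stiff,0.9703981143901068,0.0032055280913444394,4
MEGATRON_10,4.5,heterogeneous,1.1505841192757678,0.002789485140458155,4
MEGATRON_10,4.5,neutral,1.1453524727272208,0.003655909601964756,4
MEGATRON_10,4.5,soft,1.1690897445649533,0.0034474652682706304,4
MEGATRON_10,4.5,stiff,1.1102258888361454,0.003993697001575938,4
MEGATRON_10,4.5,very_soft,1.1900430062247405,0.003370434031825142,4
MEGATRON_10,4.5,very_stiff,1.0738215707717749,0.005363196936543378,4
MEGATRON_10,5,heterogeneous,1.1789242132567963,0.004310418388525501,4
MEGATRON_10,5,neutral,1.1700427429706426,0.005276695402725173,4
MEGATRON_10,5,soft,1.1982236947024867,0.004877460203496603,4
MEGATRON_10,5,stiff,1.1296399039303413,0.005762000687673313,4
MEGATRON_10,5,very_soft,1.222742128058074,0.004454844331354014,4
MEGATRON_10,5,very_stiff,1.090127599314365,0.005812174847560819,4
MEGATRON_12,3.5,heterogeneous,0.8469125516335194,0.002109587187213698,4
MEGATRON_12,3.5,neutral,0.8465623144945682,0.0021571737591586306,4
MEGATRON_12,3.5,soft,0.8542180390715939,0.0012720855735056057,4
MEGATRON_12,3.5,stiff,0.8318145819669713,0.002720620785351828,4
MEGATRON_12,3.5,very_soft,0.8588373793425461,6.555117816023418e-4,4
MEGATRON_12,3.5,very_stiff,0.8180494589268403,0.003078163350504745,4
MEGATRON_12,4.5,heterogeneous,0.9842074473205068,0.003625961778815253,4
MEGATRON_12,4.5,neutral,0.9787229485646589,0.004203175640915579,4
MEGATRON_12,4.5,soft,1.0016806688568607,0.003898205037915918,4
MEGATRON_12,4.5,stiff,0.9446865352618902,0.004711577616759712,4
MEGATRON_12,4.5,very_soft,1.0220839190267972,0.003389158037427576,4
MEGATRON_12,4.5,very_stiff,0.9108076133779892,0.004837253812911673,4
MEGATRON_12,5,heterogeneous,1.0178750148866005,0.004117050018602792,4
MEGATRON_12,5,neutral,1.0078918745203593,0.004990794570538491,4
MEGATRON_12,5,soft,1.0358965094977428,0.004665070414139486,4
MEGATRON_12,5,stiff,0.9661834655372179,0.005998314780625098,4
MEGATRON_12,5,very_soft,1.058527285023131,0.004209168543664071,4
MEGATRON_12,5,very_stiff,0.9274944571416237,0.005759888728500966,4
MEGATRON_9,3.5,heterogeneous,1.0952249315121807,0.0031635157142333625,4
MEGATRON_9,3.5,neutral,1.0945351806328447,0.003276737713101063,4
MEGATRON_9,3.5,soft,1.1043585686213828,0.0019376204473232467,4
MEGATRON_9,3.5,stiff,1.0782972141679636,0.003461330201194088,4
MEGATRON_9,3.5,very_soft,1.1111066236339093,0.0012004328589923139,4
MEGATRON_9,3.5,very_stiff,1.0636233648866789,0.004045306860192072,4
MEGATRON_9,4.5,heterogeneous,1.2634186002010634,0.0037191143015463386,4
MEGATRON_9,4.5,neutral,1.2555312087767398,0.004807869859897706,4
MEGATRON_9,4.5,soft,1.2830209675900899,0.004482779380780841,4
MEGATRON_9,4.5,stiff,1.214168892901382,0.005216263212170484,4
MEGATRON_9,4.5,very_soft,1.3093300847456977,0.004336049363031478,4
MEGATRON_9,4.5,very_stiff,1.1729258947672316,0.0059166661937907865,4
MEGATRON_9,5,heterogeneous,1.2985007026774107,0.004159386451922032,4
MEGATRON_9,5,neutral,1.2849277687475282,0.005755675355283914,4
MEGATRON_9,5,soft,1.3187345005107813,0.0053160647700986625,4
MEGATRON_9,5,stiff,1.2361055952644902,0.006438185515942491,4
MEGATRON_9,5,very_soft,1.3489377109770047,0.004880725797592112,4
MEGATRON_9,5,very_stiff,1.188000802938753,0.006654455002280155,4
SYNERGY,3.5,heterogeneous,0.992552820933743,0.002516034842052284,4
SYNERGY,3.5,neutral,0.9919687348250663,0.00261710858257031,4
SYNERGY,3.5,soft,1.0006120412252877,0.0018870331497654576,4
SYNERGY,3.5,stiff,0.9777496732753186,0.0034719620489528113,4
SYNERGY,3.5,very_soft,1.0072944093462795,0.001117731900682479,4
SYNERGY,3.5,very_stiff,0.964897465300855,0.003768405005847567,4
SYNERGY,4.5,heterogeneous,1.1550161673230708,0.0041658733958892715,4
SYNERGY,4.5,neutral,1.1432561551876992,0.004409266426822867,4
SYNERGY,4.5,soft,1.1700801069284443,0.004339156423918221,4
SYNERGY,4.5,stiff,1.1059273552068436,0.0047622016463569365,4
SYNERGY,4.5,very_soft,1.1952431566291997,0.0037277747656716265,4
SYNERGY,4.5,very_stiff,1.068909730327991,0.005281579747111796,4
SYNERGY,5,heterogeneous,1.190966988470289,0.003662868893272889,4
SYNERGY,5,neutral,1.1746636951366827,0.004980406112295789,4
SYNERGY,5,soft,1.2064432047233535,0.004496600022922043,4
SYNERGY,5,stiff,1.1289984498686518,0.00548871268368092,4
SYNERGY,5,very_soft,1.2357299721496737,0.004215329761118598,4
SYNERGY,5,very_stiff,1.0853190128911065,0.0058068620856620585,4
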