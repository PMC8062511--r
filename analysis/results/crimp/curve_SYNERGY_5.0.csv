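outer_diameter_mm,radial_force_N,design,diameter
4.72364314580871,0,SYNERGY,5
4.715615295879749,0.19967070955747143,SYNERGY,5
4.707587445950788,0.398868522971642,SYNERGY,5
4.699559596021826,0.5975963919262248,SYNERGY,5
4.691531746092865,0.79585724609444,SYNERGY,5
4.683503896163904,0.9936539933580935,SYNERGY,5
4.675476046234943,1.1909895200243057,SYNERGY,5
4.6674481963059815,1.3878666910392525,SYNERGY,5
4.65942034637702,1.5842883501997855,SYNERGY,5
4.651392496448059,1.7802573203621748,SYNERGY,5
4.643364646519098,1.9757764036485537,SYNERGY,5
4.635336796590137,2.1708483816508615,SYNERGY,5
4.627308946661175,2.365476015632446,SYNERGY,5
4.619281096732214,2.559662046727171,SYNERGY,5
4.611253246803253,2.7534091961362552,SYNERGY,5
4.603225396874293,2.946720165322816,SYNERGY,5
4.5951975469453314,3.139597636204129,SYNERGY,5
4.58716969701637,3.33204427134147,SYNERGY,5
4.579141847087409,3.524062714128031,SYNERGY,5
4.571113997158448,3.7156555889744065,SYNERGY,5
4.563086147229487,3.9068255014920146,SYNERGY,5
4.555058297300525,4.0975750386745,SYNERGY,5
4.547030447371564,4.287906769076831,SYNERGY,5
4.539002597442603,4.477823242992376,SYNERGY,5
4.530974747513642,4.66732699262811,SYNERGY,5
4.5229468975846805,4.856420532277687,SYNERGY,5
4.514919047655719,5.045106358492363,SYNERGY,5
4.506891197726758,5.233386950250317,SYNERGY,5
4.498863347797797,5.421264769123739,SYNERGY,5
4.490835497868836,5.608742259444136,SYNERGY,5
4.482807647939874,5.795821848465788,SYNERGY,5
4.474779798010913,5.98250594652721,SYNERGY,5
4.466751948081952,6.168796947210996,SYNERGY,5
4.458724098152991,6.354697227501658,SYNERGY,5
4.4506962482240295,6.540209147941806,SYNERGY,5
4.442668398295068,6.7253350527864155,SYNERGY,5
4.434640548366107,6.795635450677492,SYNERGY,5
4.426612698437146,6.792057667528645,SYNERGY,5
4.418584848508185,6.788496228045787,SYNERGY,5
4.4105569985792235,6.784951056544133,SYNERGY,5
4.402529148650262,6.781422077898459,SYNERGY,5
4.394501298721301,6.777909217538033,SYNERGY,5
4.38647344879234,6.774412401441605,SYNERGY,5
4.378445598863379,6.770931556132472,SYNERGY,5
4.370417748934417,6.767466608673563,SYNERGY,5
4.362389899005456,6.764017486662608,SYNERGY,5
4.354362049076495,6.760584118227353,SYNERGY,5
4.346334199147535,6.757166432020821,SYNERGY,5
4.338306349218573,6.753764357216627,SYNERGY,5
4.330278499289612,6.750377823504352,SYNERGY,5
4.322250649360651,6.74700676108496,SYNERGY,5
4.31422279943169,6.743651100666283,SYNERGY,5
4.3061949495027285,6.7403107734585115,SYNERGY,5
4.298167099573767,6.736985711169797,SYNERGY,5
4.290139249644806,6.733675846001848,SYNERGY,5
4.282111399715845,6.730381110645609,SYNERGY,5
4.274083549786884,6.7271014382769545,SYNERGY,5
4.266055699857922,6.723836762552476,SYNERGY,5
4.258027849928961,6.72058701760526,SYNERGY,5
4.25,6.717352138040762,SYNERGY,5
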