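outer_diameter_mm,radial_force_N,design,diameter
3.2757476307698288,-0,MEGATRON_12,3.5
3.2706502132991537,0.2603610421354398,MEGATRON_12,3.5
3.2655527958284787,0.5204972020129348,MEGATRON_12,3.5
3.2604553783578036,0.7804092830432472,MEGATRON_12,3.5
3.2553579608871286,1.0400980860918378,MEGATRON_12,3.5
3.2502605434164535,1.299564409491487,MEGATRON_12,3.5
3.2451631259457785,1.5588090490544937,MEGATRON_12,3.5
3.2400657084751034,1.817832798085092,MEGATRON_12,3.5
3.2349682910044284,2.0766364473919077,MEGATRON_12,3.5
3.2298708735337534,2.3352207852998093,MEGATRON_12,3.5
3.2247734560630783,2.5935865976623527,MEGATRON_12,3.5
3.2196760385924033,2.851734667873658,MEGATRON_12,3.5
3.214578621121728,3.1096657768805045,MEGATRON_12,3.5
3.209481203651053,3.367380703194344,MEGATRON_12,3.5
3.204383786180378,3.62488022290296,MEGATRON_12,3.5
3.199286368709703,3.8821651096825174,MEGATRON_12,3.5
3.1941889512390276,4.1392361348091224,MEGATRON_12,3.5
3.1890915337683525,4.3960940671705915,MEGATRON_12,3.5
3.1839941162976775,4.65273967327813,MEGATRON_12,3.5
3.1788966988270024,4.9091737172777306,MEGATRON_12,3.5
3.1737992813563274,5.165396960961832,MEGATRON_12,3.5
3.1687018638856523,5.421410163780624,MEGATRON_12,3.5
3.1636044464149773,5.677214082853506,MEGATRON_12,3.5
3.1585070289443022,5.932809472980409,MEGATRON_12,3.5
3.153409611473627,6.188197086652883,MEGATRON_12,3.5
3.148312194002952,6.443377674065555,MEGATRON_12,3.5
3.143214776532277,6.6983519831269955,MEGATRON_12,3.5
3.138117359061602,6.9531207594709095,MEGATRON_12,3.5
3.133019941590927,7.207684746467263,MEGATRON_12,3.5
3.127922524120252,7.4620446852329305,MEGATRON_12,3.5
3.122825106649577,7.716201314642936,MEGATRON_12,3.5
3.117727689178902,7.970155371341016,MEGATRON_12,3.5
3.112630271708227,8.223907589750507,MEGATRON_12,3.5
3.1075328542375518,8.477458702085183,MEGATRON_12,3.5
3.1024354367668767,8.730809438359673,MEGATRON_12,3.5
3.0973380192962017,8.983960526400281,MEGATRON_12,3.5
3.0922406018255266,9.236912691855396,MEGATRON_12,3.5
3.0871431843548516,9.489666658206035,MEGATRON_12,3.5
3.0820457668841765,9.742223146776444,MEGATRON_12,3.5
3.0769483494135015,9.994582876744134,MEGATRON_12,3.5
3.0718509319428264,10.246746565150564,MEGATRON_12,3.5
3.0667535144721514,10.49871492691115,MEGATRON_12,3.5
3.0616560970014763,10.750488674825736,MEGATRON_12,3.5
3.0565586795308013,11.002068519588558,MEGATRON_12,3.5
3.0514612620601262,11.253455169798421,MEGATRON_12,3.5
3.0463638445894508,11.39346126676786,MEGATRON_12,3.5
3.0412664271187757,11.392102176887544,MEGATRON_12,3.5
3.0361690096481007,11.390749279919428,MEGATRON_12,3.5
3.0310715921774256,11.389402565364064,MEGATRON_12,3.5
3.0259741747067506,11.388062022766157,MEGATRON_12,3.5
3.0208767572360755,11.386727641714367,MEGATRON_12,3.5
3.0157793397654005,11.385399411841151,MEGATRON_12,3.5
3.0106819222947254,11.384077322822566,MEGATRON_12,3.5
3.0055845048240504,11.382761364378103,MEGATRON_12,3.5
3.0004870873533753,11.381451526270522,MEGATRON_12,3.5
2.9953896698827003,11.38014779830566,MEGATRON_12,3.5
2.9902922524120252,11.378850170332283,MEGATRON_12,3.5
2.98519483494135,11.377558632241879,MEGATRON_12,3.5
2.980097417470675,11.376273173968523,MEGATRON_12,3.5
2.975,11.374993785488687,MEGATRON_12,3.5
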