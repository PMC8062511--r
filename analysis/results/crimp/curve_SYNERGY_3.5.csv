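outer_diameter_mm,radial_force_N,design,diameter
3.199150768485525,-0,SYNERGY,3.5
3.195351602917974,0.07554817769649422,SYNERGY,3.5
3.1915524373504223,0.15105080157646641,SYNERGY,3.5
3.187753271782871,0.22650799144193015,SYNERGY,3.5
3.18395410621532,0.3019198668264485,SYNERGY,3.5
3.1801549406477685,0.3772865469960346,SYNERGY,3.5
3.1763557750802174,0.45260815095006396,SYNERGY,3.5
3.1725566095126663,0.5278847974223045,SYNERGY,3.5
3.1687574439451147,0.6031166048817715,SYNERGY,3.5
3.1649582783775636,0.6783036915337334,SYNERGY,3.5
3.161159112810012,0.7534461753206111,SYNERGY,3.5
3.157359947242461,0.8285441739229104,SYNERGY,3.5
3.15356078167491,0.9035978047601476,SYNERGY,3.5
3.1497616161073583,0.9786071849917926,SYNERGY,3.5
3.145962450539807,1.0535724315181882,SYNERGY,3.5
3.142163284972256,1.1284936609814356,SYNERGY,3.5
3.1383641194047045,1.2033709897663258,SYNERGY,3.5
3.1345649538371534,1.278204534001267,SYNERGY,3.5
3.1307657882696023,1.3529944095591435,SYNERGY,3.5
3.1269666227020507,1.4277407320583213,SYNERGY,3.5
3.1231674571344996,1.5024436168633477,SYNERGY,3.5
3.1193682915669485,1.5771031790860888,SYNERGY,3.5
3.115569125999397,1.6517195335864687,SYNERGY,3.5
3.111769960431846,1.7262927949733504,SYNERGY,3.5
3.1079707948642943,1.80082307760554,SYNERGY,3.5
3.104171629296743,1.875310495592508,SYNERGY,3.5
3.100372463729192,1.9497551627954208,SYNERGY,3.5
3.0965732981616405,2.024157192827939,SYNERGY,3.5
3.0927741325940894,2.09851669905703,SYNERGY,3.5
3.0889749670265383,2.172833794604006,SYNERGY,3.5
3.0851758014589867,2.2471085923452128,SYNERGY,3.5
3.0813766358914356,2.321341204912968,SYNERGY,3.5
3.0775774703238845,2.3955317446964397,SYNERGY,3.5
3.073778304756333,2.469680323842477,SYNERGY,3.5
3.069979139188782,2.543787054256454,SYNERGY,3.5
3.0661799736212307,2.6178520476031095,SYNERGY,3.5
3.062380808053679,2.691875415307431,SYNERGY,3.5
3.058581642486128,2.765857268555446,SYNERGY,3.5
3.0547824769185765,2.8397977182951295,SYNERGY,3.5
3.0509833113510254,2.913696875237171,SYNERGY,3.5
3.0471841457834743,2.9875548498558473,SYNERGY,3.5
3.0433849802159227,3.0613717523897965,SYNERGY,3.5
3.0395858146483716,3.135147692842956,SYNERGY,3.5
3.0357866490808205,3.2088827809852605,SYNERGY,3.5
3.031987483513269,3.282577126353558,SYNERGY,3.5
3.028188317945718,3.356230838252324,SYNERGY,3.5
3.0243891523781667,3.429844025754614,SYNERGY,3.5
3.020589986810615,3.5034167977027257,SYNERGY,3.5
3.016790821243064,3.5769492627091517,SYNERGY,3.5
3.012991655675513,3.6504415291572103,SYNERGY,3.5
3.0091924901079614,3.7238937052020478,SYNERGY,3.5
3.0053933245404103,3.7973058987712576,SYNERGY,3.5
3.001594158972859,3.8706782175658048,SYNERGY,3.5
2.9977949934053076,3.944010769060766,SYNERGY,3.5
2.9939958278377565,4.017303660506054,SYNERGY,3.5
2.990196662270205,4.090556998927342,SYNERGY,3.5
2.986397496702654,4.163770891126746,SYNERGY,3.5
2.9825983311351028,4.236945443683641,SYNERGY,3.5
2.978799165567551,4.310080762955419,SYNERGY,3.5
2.975,4.383176955078303,SYNERGY,3.5
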