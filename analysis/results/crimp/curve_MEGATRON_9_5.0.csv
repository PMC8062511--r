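outer_diameter_mm,radial_force_N,design,diameter
4.7469443381536,-0,MEGATRON_9,5
4.738521552761166,0.2700419170038703,MEGATRON_9,5
4.730098767368733,0.5393206964773587,MEGATRON_9,5
4.721675981976299,0.8078417606827046,MEGATRON_9,5
4.713253196583865,1.075610484704083,MEGATRON_9,5
4.7048304111914305,1.3426321969904547,MEGATRON_9,5
4.696407625798997,1.6089121798911148,MEGATRON_9,5
4.687984840406563,1.8744556701836164,MEGATRON_9,5
4.679562055014129,2.139267859594243,MEGATRON_9,5
4.671139269621695,2.4033538953117666,MEGATRON_9,5
4.662716484229262,2.666718880493601,MEGATRON_9,5
4.6542936988368275,2.929367874765577,MEGATRON_9,5
4.645870913444393,3.1913058947142137,MEGATRON_9,5
4.637448128051959,3.4525379143729227,MEGATRON_9,5
4.629025342659526,3.713068865701151,MEGATRON_9,5
4.620602557267092,3.972903639057312,MEGATRON_9,5
4.612179771874658,4.232047083665042,MEGATRON_9,5
4.603756986482224,4.4905040080732475,MEGATRON_9,5
4.59533420108979,4.748279180610145,MEGATRON_9,5
4.586911415697356,5.005377329830989,MEGATRON_9,5
4.578488630304922,5.261803144959731,MEGATRON_9,5
4.570065844912488,5.5175612763249875,MEGATRON_9,5
4.561643059520055,5.772656335790077,MEGATRON_9,5
4.553220274127621,6.0270928971772975,MEGATRON_9,5
4.5447974887351865,6.28087549668667,MEGATRON_9,5
4.536374703342752,6.534008633309016,MEGATRON_9,5
4.527951917950319,6.786496769233673,MEGATRON_9,5
4.519529132557885,7.038344330250764,MEGATRON_9,5
4.511106347165451,7.289555706148258,MEGATRON_9,5
4.502683561773017,7.540135251103777,MEGATRON_9,5
4.4942607763805835,7.790087284071124,MEGATRON_9,5
4.485837990988149,8.020340015241244,MEGATRON_9,5
4.477415205595715,8.015195711665863,MEGATRON_9,5
4.468992420203281,8.010077352163137,MEGATRON_9,5
4.460569634810848,8.004984794784693,MEGATRON_9,5
4.452146849418414,7.999917898788271,MEGATRON_9,5
4.44372406402598,7.9948765246250275,MEGATRON_9,5
4.4353012786335455,7.989860533927021,MEGATRON_9,5
4.426878493241112,7.984869789494839,MEGATRON_9,5
4.418455707848678,7.979904155285402,MEGATRON_9,5
4.410032922456244,7.974963496399927,MEGATRON_9,5
4.40161013706381,7.970047679072022,MEGATRON_9,5
4.393187351671377,7.965156570655952,MEGATRON_9,5
4.3847645662789425,7.960290039615052,MEGATRON_9,5
4.376341780886508,7.955447955510288,MEGATRON_9,5
4.367918995494074,7.950630188988952,MEGATRON_9,5
4.359496210101641,7.945836611773521,MEGATRON_9,5
4.351073424709207,7.941067096650631,MEGATRON_9,5
4.342650639316773,7.936321517460218,MEGATRON_9,5
4.334227853924339,7.931599749084773,MEGATRON_9,5
4.325805068531905,7.926901667438744,MEGATRON_9,5
4.317382283139471,7.92222714945807,MEGATRON_9,5
4.308959497747037,7.917576073089833,MEGATRON_9,5
4.300536712354603,7.91294831728207,MEGATRON_9,5
4.29211392696217,7.908343761973671,MEGATRON_9,5
4.283691141569736,7.903762288084435,MEGATRON_9,5
4.2752683561773015,7.899203777505231,MEGATRON_9,5
4.266845570784868,7.894668113088298,MEGATRON_9,5
4.258422785392434,7.890155178637641,MEGATRON_9,5
4.25,7.885664858899568,MEGATRON_9,5
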