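outer_diameter_mm,radial_force_N,design,diameter
4.277639097297144,-0,MEGATRON_10,4.5
4.269967248190413,0.3639983994156245,MEGATRON_10,4.5
4.262295399083682,0.727157647003551,MEGATRON_10,4.5
4.254623549976951,1.0894830075473652,MEGATRON_10,4.5
4.246951700870219,1.4509797070747503,MEGATRON_10,4.5
4.239279851763488,1.811652933241128,MEGATRON_10,4.5
4.231608002656757,2.171507835708751,MEGATRON_10,4.5
4.223936153550025,2.530549526521476,MEGATRON_10,4.5
4.216264304443294,2.8887830804746035,MEGATRON_10,4.5
4.208592455336563,3.2462135354810817,MEGATRON_10,4.5
4.200920606229832,3.6028458929328537,MEGATRON_10,4.5
4.193248757123101,3.9586851180580482,MEGATRON_10,4.5
4.185576908016369,4.313736140274457,MEGATRON_10,4.5
4.177905058909638,4.668003853537795,MEGATRON_10,4.5
4.170233209802907,5.021493116687217,MEGATRON_10,4.5
4.162561360696175,5.37420875378596,MEGATRON_10,4.5
4.154889511589444,5.726155554457914,MEGATRON_10,4.5
4.147217662482713,6.0773382742213,MEGATRON_10,4.5
4.139545813375982,6.427761634817073,MEGATRON_10,4.5
4.131873964269251,6.777430324534703,MEGATRON_10,4.5
4.124202115162519,7.1263489985337465,MEGATRON_10,4.5
4.116530266055788,7.474522279161417,MEGATRON_10,4.5
4.108858416949056,7.821954756267295,MEGATRON_10,4.5
4.101186567842325,8.168650987513411,MEGATRON_10,4.5
4.0935147187355945,8.514615498681918,MEGATRON_10,4.5
4.085842869628863,8.859852783978168,MEGATRON_10,4.5
4.078171020522132,9.20436730633126,MEGATRON_10,4.5
4.0704991714154,9.548163497690462,MEGATRON_10,4.5
4.062827322308669,9.891245759318775,MEGATRON_10,4.5
4.055155473201937,10.233618462082882,MEGATRON_10,4.5
4.047483624095206,10.453323649193914,MEGATRON_10,4.5
4.039811774988475,10.448253325559438,MEGATRON_10,4.5
4.032139925881744,10.443207689991102,MEGATRON_10,4.5
4.024468076775013,10.43818662962795,MEGATRON_10,4.5
4.016796227668282,10.43319003245373,MEGATRON_10,4.5
4.00912437856155,10.428217787289226,MEGATRON_10,4.5
4.001452529454819,10.423269783784663,MEGATRON_10,4.5
3.9937806803480873,10.41834591241227,MEGATRON_10,4.5
3.986108831241356,10.413446064458824,MEGATRON_10,4.5
3.978436982134625,10.408570132018346,MEGATRON_10,4.5
3.9707651330278937,10.40371800798487,MEGATRON_10,4.5
3.9630932839211623,10.398889586045268,MEGATRON_10,4.5
3.955421434814431,10.39408476067218,MEGATRON_10,4.5
3.9477495857076996,10.389303427117015,MEGATRON_10,4.5
3.9400777366009687,10.38454548140301,MEGATRON_10,4.5
3.9324058874942374,10.379810820318395,MEGATRON_10,4.5
3.924734038387506,10.375099341409625,MEGATRON_10,4.5
3.9170621892807747,10.370410942974674,MEGATRON_10,4.5
3.9093903401740437,10.365745524056411,MEGATRON_10,4.5
3.9017184910673124,10.361102984436057,MEGATRON_10,4.5
3.894046641960581,10.356483224626695,MEGATRON_10,4.5
3.8863747928538497,10.351886145866867,MEGATRON_10,4.5
3.8787029437471188,10.347311650114237,MEGATRON_10,4.5
3.8710310946403874,10.342759640039315,MEGATRON_10,4.5
3.863359245533656,10.338230019019269,MEGATRON_10,4.5
3.8556873964269247,10.333722691131767,MEGATRON_10,4.5
3.8480155473201934,10.329237561148929,MEGATRON_10,4.5
3.8403436982134624,10.324774534531322,MEGATRON_10,4.5
3.832671849106731,10.320333517422005,MEGATRON_10,4.5
3.8249999999999997,10.315914416640688,MEGATRON_10,4.5
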