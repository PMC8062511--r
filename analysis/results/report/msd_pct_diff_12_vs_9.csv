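diameter,plaque,mean_pct_diff,sem_pct_diff,n_seeds
3.5,heterogeneous,2.0085117639366725,0.0816426844564294,4
3.5,neutral,2.02960146810132,0.08927263122604233,4
3.5,soft,1.959554816994784,0.053166670933749015,4
3.5,stiff,1.8905288093764634,0.051127083424799595,4
3.5,very_soft,1.8393002437978712,0.044431517363529176,4
3.5,very_stiff,1.6778469466665942,0.06421086986735333,4
4.5,heterogeneous,2.3681778208175888,0.11032235190006469,4
4.5,neutral,2.4521486272447612,0.05059300242408208,4
4.5,soft,2.479950176256576,0.04957370584197669,4
4.5,stiff,2.441915232662038,0.045079507148311375,4
4.5,very_soft,2.3300444266125866,0.08271330017302017,4
4.5,very_stiff,2.38195763391041,0.05425300302904053,4
5,heterogeneous,2.9063184660317374,0.13279032408541266,4
5,neutral,3.0880192696206366,0.0796136403882108,4
5,soft,3.035651335610066,0.05326627684386358,4
5,stiff,3.027839177109096,0.09933654287559629,4
5,very_soft,2.6932598580691445,0.05744941148932185,4
5,very_stiff,3.1709220575668997,0.09400930050798205,4
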