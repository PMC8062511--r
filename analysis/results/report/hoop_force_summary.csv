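design,diameter,plaque,mean,sem,n
MEGATRON_10,3.5,heterogeneous,0.07277011692074867,0,4
MEGATRON_10,3.5,neutral,0.07277011692074867,0,4
MEGATRON_10,3.5,soft,0.07277011692074867,0,4
MEGATRON_10,3.5,stiff,0.07277011692074867,0,4
MEGATRON_10,3.5,very_soft,0.07277011692074867,0,4
MEGATRON_10,3.5,very_stiff,0.07277011692074867,0,4
MEGATRON_10,4.5,heterogeneous,0.08068371146986524,0,4
MEGATRON_10,4.5,neutral,0.08068371146986524,0,4
MEGATRON_10,4.5,soft,0.08068371146986524,0,4
MEGATRON_10,4.5,stiff,0.08068371146986524,0,4
MEGATRON_10,4.5,very_soft,0.08068371146986524,0,4
MEGATRON_10,4.5,very_stiff,0.08068371146986524,0,4
MEGATRON_10,5,heterogeneous,0.0863683515932966,0,4
MEGATRON_10,5,neutral,0.0863683515932966,0,4
MEGATRON_10,5,soft,0.0863683515932966,0,4
MEGATRON_10,5,stiff,0.0863683515932966,0,4
MEGATRON_10,5,very_soft,0.0863683515932966,0,4
MEGATRON_10,5,very_stiff,0.0863683515932966,0,4
MEGATRON_12,3.5,heterogeneous,0.09044018351781308,0,4
MEGATRON_12,3.5,neutral,0.09044018351781308,0,4
MEGATRON_12,3.5,soft,0.09044018351781308,0,4
MEGATRON_12,3.5,stiff,0.09044018351781308,0,4
MEGATRON_12,3.5,very_soft,0.09044018351781308,0,4
MEGATRON_12,3.5,very_stiff,0.09044018351781308,0,4
MEGATRON_12,4.5,heterogeneous,0.0994163521227244,0,4
MEGATRON_12,4.5,neutral,0.0994163521227244,0,4
MEGATRON_12,4.5,soft,0.0994163521227244,0,4
MEGATRON_12,4.5,stiff,0.0994163521227244,0,4
MEGATRON_12,4.5,very_soft,0.0994163521227244,0,4
MEGATRON_12,4.5,very_stiff,0.0994163521227244,0,4
MEGATRON_12,5,heterogeneous,0.1055941202452823,0,4
MEGATRON_12,5,neutral,0.1055941202452823,0,4
MEGATRON_12,5,soft,0.1055941202452823,0,4
MEGATRON_12,5,stiff,0.1055941202452823,0,4
MEGATRON_12,5,very_soft,0.1055941202452823,0,4
MEGATRON_12,5,very_stiff,0.1055941202452823,0,4
MEGATRON_9,3.5,heterogeneous,0.04853784789191493,0,4
MEGATRON_9,3.5,neutral,0.04853784789191493,0,4
MEGATRON_9,3.5,soft,0.04853784789191493,0,4
MEGATRON_9,3.5,stiff,0.04853784789191493,0,4
MEGATRON_9,3.5,very_soft,0.04853784789191493,0,4
MEGATRON_9,3.5,very_stiff,0.04853784789191493,0,4
MEGATRON_9,4.5,heterogeneous,0.06093252392350679,0,4
MEGATRON_9,4.5,neutral,0.06093252392350679,0,4
MEGATRON_9,4.5,soft,0.06093252392350679,0,4
MEGATRON_9,4.5,stiff,0.06093252392350679,0,4
MEGATRON_9,4.5,very_soft,0.06093252392350679,0,4
MEGATRON_9,4.5,very_stiff,0.06093252392350679,0,4
MEGATRON_9,5,heterogeneous,0.06466447612479084,0,4
MEGATRON_9,5,neutral,0.06466447612479084,0,4
MEGATRON_9,5,soft,0.06466447612479084,0,4
MEGATRON_9,5,stiff,0.06466447612479084,0,4
MEGATRON_9,5,very_soft,0.06466447612479084,0,4
MEGATRON_9,5,very_stiff,0.06466447612479084,0,4
SYNERGY,3.5,heterogeneous,0.03431403240763377,0,4
SYNERGY,3.5,neutral,0.03431403240763377,0,4
SYNERGY,3.5,soft,0.03431403240763377,0,4
SYNERGY,3.5,stiff,0.03431403240763377,0,4
SYNERGY,3.5,very_soft,0.03431403240763377,0,4
SYNERGY,3.5,very_stiff,0.03431403240763377,0,4
SYNERGY,4.5,heterogeneous,0.05047849722723732,0,4
SYNERGY,4.5,neutral,0.05047849722723732,0,4
SYNERGY,4.5,soft,0.05047849722723732,0,4
SYNERGY,4.5,stiff,0.05047849722723732,0,4
SYNERGY,4.5,very_soft,0.05047849722723732,0,4
SYNERGY,4.5,very_stiff,0.05047849722723732,0,4
SYNERGY,5,heterogeneous,0.05320014625803458,0,4
SYNERGY,5,neutral,0.05320014625803458,0,4
SYNERGY,5,soft,0.05320014625803458,0,4
SYNERGY,5,stiff,0.05320014625803458,0,4
SYNERGY,5,very_soft,0.05320014625803458,0,4
SYNERGY,5,very_stiff,0.05320014625803458,0,4
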