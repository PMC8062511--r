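design,diameter,max_hoop_force_N,normalized_hoop_force_N_mm
MEGATRON_9,3.5,0.9581371173864007,0.04853784789191493
MEGATRON_9,4.5,1.202808022250024,0.06093252392350679
MEGATRON_9,5,1.2764767587033712,0.06466447612479084
MEGATRON_10,3.5,1.5005198109058375,0.07277011692074867
MEGATRON_10,4.5,1.6636981305086211,0.08068371146986524
MEGATRON_10,5,1.780915409853776,0.0863683515932966
MEGATRON_12,3.5,1.8133256795321526,0.09044018351781309
MEGATRON_12,4.5,1.9932978600606244,0.0994163521227244
MEGATRON_12,5,2.11716211091791,0.1055941202452823
SYNERGY,3.5,0.6976042788471944,0.03431403240763377
SYNERGY,4.5,1.0262278486297347,0.05047849722723732
SYNERGY,5,1.0815589734258428,0.05320014625803458
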