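MEGATRON_9:
  name: MEGATRON_9
  peaks: 9
  rings: 12
  links_total: 36
  strut_thickness: 0.089
  strut_width: 0.089
  crimped_id: 0.84
  crimped_length: 19.74
  link_gap: 0.3
MEGATRON_10:
  name: MEGATRON_10
  peaks: 10
  rings: 14
  links_total: 28
  strut_thickness: 0.089
  strut_width: 0.089
  crimped_id: 0.84
  crimped_length: 20.62
  link_gap: 0.3
MEGATRON_12:
  name: MEGATRON_12
  peaks: 12
  rings: 15
  links_total: 50
  strut_thickness: 0.089
  strut_width: 0.089
  crimped_id: 0.84
  crimped_length: 20.05
  link_gap: 0.3
SYNERGY:
  name: SYNERGY
  peaks: 10
  rings: 13
  links_total: 36
  strut_thickness: 0.081
  strut_width: 0.081
  crimped_id: 0.84
  crimped_length: 20.33
  link_gap: 0.3
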