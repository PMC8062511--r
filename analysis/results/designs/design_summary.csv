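design,peaks,rings,links_total,strut_thickness_um,crimped_length_mm,crown_height_mm,n_cells,strut_area_mm2,max_expansion_diameter_mm
MEGATRON_9,9,12,36,89,19.74,1.3699999999999999,36,27.480036443540445,7.855022709029048
MEGATRON_10,10,14,28,89,20.62,1.1942857142857144,28,30.728736771519223,7.601730912492775
MEGATRON_12,12,15,50,89,20.05,1.0566666666666669,50,35.412792031668666,8.059567586516627
SYNERGY,10,13,36,81,20.33,1.2869230769230766,36,28.146718904295597,8.196989831730383
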