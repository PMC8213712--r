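# Dynamic change of LULC types 2017-2025 under the three scenarios of the
# Weishan case study: signed area change (ha) and the printed single
# land-use dynamic degree (% per year). The printed dynamics are internally
# consistent with an annualization span of 5 years.
scenario,class_code,area_change_ha,single_dynamics_pct
natural,1,-2801.25,-1.95
natural,2,5515.83,3.04
natural,3,-3168.18,-6.46
natural,4,-65.61,-1.12
natural,5,7817.13,4.98
natural,6,-7302.15,-14.2
ecological,1,-4172.49,-2.91
ecological,2,6548.31,3.61
ecological,3,-3434.58,-7.01
ecological,4,-166.05,-2.84
ecological,5,7978.77,5.08
ecological,6,-6758.19,-13.14
farmland,1,-629.73,-0.44
farmland,2,3867.03,2.13
farmland,3,-3370.5,-6.88
farmland,4,-85.05,-1.46
farmland,5,7528.41,4.79
farmland,6,-7314.39,-14.23
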