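# Conversion elasticity (ELAS) of each LULC class under the three scenarios
# of the Weishan case study, as calibrated in the source analysis.
scenario,class_code,elas
natural,1,0.7
natural,2,0.5
natural,3,0.9
natural,4,0.6
natural,5,0.6
natural,6,0.55
ecological,1,0.7
ecological,2,0.6
ecological,3,0.9
ecological,4,0.5
ecological,5,0.7
ecological,6,0.6
farmland,1,0.8
farmland,2,0.5
farmland,3,0.9
farmland,4,0.6
farmland,5,0.6
farmland,6,0.5
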