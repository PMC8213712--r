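# Projected 2025 class-area demands (ha) for the Weishan coal-mining study
# area under the three policy scenarios of the case study.
scenario,class_code,class_name,area_ha
natural,1,farmland,25907.39
natural,2,other agricultural land,41817.72
natural,3,urban and rural construction land,6642.71
natural,4,subsided seeper area,1119.64
natural,5,water area,39199.37
natural,6,tidal wetland,2995.01
ecological,1,farmland,24535.92
ecological,2,other agricultural land,42839.93
ecological,3,urban and rural construction land,6385.32
ecological,4,subsided seeper area,1020.68
ecological,5,water area,39362.02
ecological,6,tidal wetland,3537.96
farmland,1,farmland,28074.34
farmland,2,other agricultural land,40163.25
farmland,3,urban and rural construction land,6449.67
farmland,4,subsided seeper area,1099.93
farmland,5,water area,38918.11
farmland,6,tidal wetland,2976.55
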