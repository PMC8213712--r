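# Published binary-logistic regression coefficients (standardized drivers)
# for the six LULC classes of the Weishan coal-mining study area. included=0
# marks drivers the published table leaves out for that class (structural
# zero). The slope row of the source table is typographically ambiguous for
# the subsided-seeper and water classes; those cells carry uncertain=1
# (subsided treated as excluded, water as -0.051).
driver,class_code,beta,included,uncertain
dist_residential,1,-0.974,1,0
dist_residential,2,0.136,1,0
dist_residential,3,-3.282,1,0
dist_residential,4,1.197,1,0
dist_residential,5,1.564,1,0
dist_residential,6,0.562,1,0
dist_mines,1,NA,0,0
dist_mines,2,0.316,1,0
dist_mines,3,-1.112,1,0
dist_mines,4,-5.813,1,0
dist_mines,5,-0.419,1,0
dist_mines,6,1.274,1,0
dist_roads,1,0.894,1,0
dist_roads,2,-0.101,1,0
dist_roads,3,-0.216,1,0
dist_roads,4,-0.833,1,0
dist_roads,5,-1.221,1,0
dist_roads,6,-0.603,1,0
dist_rivers,1,-1.769,1,0
dist_rivers,2,-0.738,1,0
dist_rivers,3,NA,0,0
dist_rivers,4,-1.562,1,0
dist_rivers,5,3.396,1,0
dist_rivers,6,NA,0,0
dist_ditches,1,1.588,1,0
dist_ditches,2,0.655,1,0
dist_ditches,3,0.207,1,0
dist_ditches,4,0.481,1,0
dist_ditches,5,-3.337,1,0
dist_ditches,6,-2.287,1,0
elevation,1,-0.19,1,0
elevation,2,0.045,1,0
elevation,3,0.044,1,0
elevation,4,0.571,1,0
elevation,5,0.214,1,0
elevation,6,0.225,1,0
slope,1,-0.136,1,0
slope,2,0.104,1,0
slope,3,-0.057,1,0
slope,4,NA,0,1
slope,5,-0.051,1,1
slope,6,0.275,1,0
constant,1,-0.009,1,0
constant,2,-1.284,1,0
constant,3,-5.483,1,0
constant,4,-8.94,1,0
constant,5,-1.779,1,0
constant,6,-4.237,1,0
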