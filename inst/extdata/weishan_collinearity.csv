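# Published tolerance / variance-inflation-factor collinearity diagnostics
# of the seven driving factors for the Weishan study area.
driver,tolerance,vif
dist_residential,0.563,1.777
dist_mines,0.351,2.846
dist_roads,0.228,4.387
dist_rivers,0.207,4.833
dist_ditches,0.329,3.037
elevation,0.888,1.126
slope,0.874,1.144
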