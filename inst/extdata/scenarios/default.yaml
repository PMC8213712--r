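# Default synthetic pipeline configuration: a 120 x 120 landscape at 60 m,
# an 11-year generated map pair, a 9-year projection horizon and the three
# policy scenarios with their case-study ELAS vectors.
seed: 1
geometry:
  nrows: 120
  ncols: 120
  cellsize: 60
transition_period: 11
horizon_years: 9
scenarios:
  - name: natural development
    elas: [0.7, 0.5, 0.9, 0.6, 0.6, 0.55]
    allowed: all
  - name: ecological protection
    elas: [0.7, 0.6, 0.9, 0.5, 0.7, 0.6]
    allowed: all
  - name: farmland protection
    elas: [0.8, 0.5, 0.9, 0.6, 0.6, 0.5]
    allowed: all
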