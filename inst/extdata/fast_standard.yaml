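# Reference run: fast-pace leukemia, single 7+3 induction, full grid.
pace: fast
arm: standard
grid:
  min: 0
  max: 10
  step: 0.1
horizon: 2000
d2_l: calibrate
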