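# Full-scale configuration stub. These sizes reproduce the scale of the
# original experiments (a quadratic tissue layer resolved with hundreds of
# finite-difference points per side and hour-long pacing conditioning).
# They are far beyond a desk-scale single-CPU session; run on a cluster.
grid:
  nx: 401
  ny: 401
  hs: 0.25
  D: 0.154
electrics:
  dt: 0.02
  init_beats: 600
protocol:
  name: spiral
  mode: contracting
  duration: 10000
  gs_values: [0.0, 0.005, 0.01, 0.015, 0.02, 0.025, 0.03]
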