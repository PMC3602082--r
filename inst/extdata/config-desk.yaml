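# Desk-scale configuration: reduced sheet sizes sized for a single CPU.
# All omitted keys take the package defaults (see load_config()).
grid:
  nx: 61
  ny: 21
  hs: 0.5
  D: 0.154
electrics:
  dt: 0.02
protocol:
  name: sheet
  mode: constant_stretch
  period: 600
  gs_values: [0.0, 0.01, 0.02, 0.03]
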