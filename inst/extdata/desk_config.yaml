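# Example network configuration: the 1:100 desk-scale model.
scale:
  factor: 0.01
geometry:
  axis_length_mm: 10
  transverse_extent_mm: 1
populations:
  GC:  {full_count: 1000000}
  BC:  {full_count: 6000}
  MC:  {full_count: 30000}
  MEC: {full_count: 56000}
  LEC: {full_count: 56000}
stimulus:
  rate_hz: 3
  ramp_ms: 1000
  duration_ms: 4000
network:
  include_mc: false
  mc_topography: topographic
rng:
  master_seed: 1
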