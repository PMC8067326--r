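# 3D run: sphere of radius 5 with a single central-offset granule.
# h_target is coarser than in 2D to keep the tetrahedral mesh tractable.
domain:
  shape: sphere
  size_params: 5.0
  h_target: 0.4
granules:
  - center: [1.5, 1.5, 0.0]
    radius: 1.0
    value: 1.0
solver:
  gamma: 1.0
  dt: 0.001
  n_steps: 1500
  seed: 1
output:
  record_every: 250
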