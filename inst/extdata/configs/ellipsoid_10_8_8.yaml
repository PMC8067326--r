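# 3D ellipsoid companion of the ellipse run; the third axis (not dictated by
# the 2D protocol) is set equal to the minor axis.
domain:
  shape: ellipsoid
  size_params: [10.0, 8.0, 8.0]
  h_target: 0.4
solver:
  gamma: 1.0
  dt: 0.005
  n_steps: 60
  seed: 1
output:
  record_every: 10
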