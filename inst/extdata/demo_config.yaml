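# Demo: unit square, parabolic intrinsic kernel (half-support 0.75),
# no-go boundaries; reduced-scale ensemble that runs in minutes.
domain:
  type: polygon
  side: 1
distribution:
  family: parabolic
  a: 0.75
boundary_condition: no_go
n_steps: 10000
n_runs: 50
burn_in: 100
seed: 1
bins: 60
shaper_floor: 0.01
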