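n_columns: 4
coupling_strength: 15.0
constant_input: 75.0
noise_intensity: 350.0
noise_correlation_time: 0.14999999999999999
integration_step: 0.001
simulation_length: 1010.0
transient_length: 10.0
seed: 1
record_stride: 1
driving_mode: sine
driving_amplitude: 45.0
driving_frequency: 0.25
column:
  A: 3.25
  B: 22.0
  a: 100.0
  b: 50.0
  C1: 135.0
  C2: 108.0
  C3: 33.75
  C4: 33.75
  e0: 2.5
  v0: 6.0
  r: 0.56000000000000005
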