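# Base simulated experiment: three-layer phantom, Telesto-like system
# response, 50-pixel vertical shift, 200 lateral A-scans, speckle + shot
# noise at 80 dB SNR.
grid:
  p: 512
  zmax: 2.5
phantom:
  boundaries: [0.073, 0.561, 1.050, 2.5]
  mu: [1.0, 2.0, 4.0]
  refractive_index: 1.0
detection:
  k: 1000.0
  alpha: 0.75
  beta: 0.75
  L0: 5.0
system:
  z0: 0.7324
  zR: 0.3662
  lambda0: 1.31e-06
  dlambda: 7.1875e-11
  deltalambda: 1.1055e-10
noise:
  snr_db: 80.0
  speckle: true
  shot: true
  floor_db: -30.0
  seed: 1
shifts: [0, 50]
n_lateral: 200
basis_fit:
  n_basis: 20
attenuation:
  enabled: true
  margin: 5
  refractive_index: 1.0
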