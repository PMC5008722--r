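name: high_density
fov: {width_px: 64, height_px: 64, pixel_size_nm: 100}
sample:
  pattern: uniform_random
  density: 1000         # emitters per um^2, over the central 2 x 2 um patch
  brightness: 500
  region: [22, 22, 42, 42]
photophysics: {tau_on: 0.02, tau_off: 0.2, t_bleach: .inf}
optics: {numerical_aperture: 1.2, emission_wavelength_nm: 520}
camera:
  quantum_efficiency: 0.7
  gain: 30
  dark_noise_sd: 2
  baseline: 100
  frame_time_s: 0.01
  em_gain: true
acquisition: {n_frames: 1000, background: 10}
sofi: {orders: [2, 3, 4, 5, 6, 7], iterations: 10}
storm: {detection_threshold: 5, width_tolerance: 0.5}
seed: 1
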