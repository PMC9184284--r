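# Simulated BSA study in a 100 x 27 nm nanochannel
channel:
  name: I
  fov_length: 15000
species:
  - name: BSA
    mw: 66
    r_s: 3.5
optics:
  psf_sigma: 100
  pixel_pitch: 30
  noise_rel: 5.0e-5
  frame_rate: 200
simulate:
  n_traj: 50
  n_frames: 500
track:
  kappa: 5
  min_n: 50
report:
  fields: [mw_kDa, rs_nm]
  n_components: 1
seed: 42
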