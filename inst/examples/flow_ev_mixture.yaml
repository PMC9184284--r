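# Flow-mode mixture of a lipoprotein-like and an EV-like population in a
# wide channel: pressure-driven drift plus diffusion; the two species
# separate in (iOC, R_s).
channel:
  name: V
  fov_length: 15000
species:
  - name: lipoprotein_like
    mw: 2000
    r_s: 10
    drift_velocity: 40000
  - name: ev_like
    mw: 30000
    r_s: 45
    drift_velocity: 40000
optics:
  psf_sigma: 100
  pixel_pitch: 30
  noise_rel: 5.0e-5
  frame_rate: 200
simulate:
  n_traj: 40
  n_frames: 300
  flow: true
track:
  kappa: 5
  min_n: 50
report:
  fields: [mw_kDa, rs_nm]
  n_components: 1
seed: 42
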