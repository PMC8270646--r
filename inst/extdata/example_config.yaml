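# Example DXB run configuration.
# Geometry/timing mirror a laboratory Cu-anode setup with a
# photon-counting detector; the simulation block produces a synthetic
# blinking ring with known kinetics (rate sum = k_on + k_off = 0.6 1/s).
seed: 1
geometry:
  wavelength: 1.54        # Angstrom
  distance: 60            # mm, sample to detector
  pixel_pitch: 172        # micrometres
  beam_center: [79.5, 79.5]   # 0-based [row, col]
timing:
  frame_interval: 0.05    # s
  exposure: 0.042         # s
analysis:
  bin_size: 1             # spots here are well exposed per pixel; see the
                          # methods vignette on when to bin
  roi:
    two_theta_center: 9.75     # degrees; ring radius = L * tan(2theta)
    two_theta_halfwidth: 0.35  # degrees
  max_lag_fraction: 0.25
  detrend_policy: auto
  residual_rule: sum
  min_pixels: 20
physics:
  phi_theta: 3.18         # pm, rotational displacement (required for D_R)
  motion_class: rotational-diffusion
simulation:
  n_spots: 60
  k_on: 0.3               # 1/s
  k_off: 0.3              # 1/s
  on_intensity: 45        # photons/frame/spot over the footprint
  background: 2           # photons/pixel/frame
  psf_size: 3
  n_frames: 2000
  shape: [160, 160]
  ring:
    width: 0
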