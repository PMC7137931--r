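# Example stagescan run configuration.
# Any key omitted here falls back to default_config(); unknown keys are
# rejected. Units are µm unless noted.

seed: 1
out_dir: stagescan-out

optics:
  na: 0.5
  wavelength_nm: 530
  pixel_um: 0.386        # 20x objective, camera-plane pixel size
  fov_px: 256
  defocus_blur_um_per_um: 0.5
  vignette_strength: 0.05

actuators:
  z:
    kind: piezo
    nominal_um_per_unit: 0.05   # calibrated at the 335 g Z load
    variability_frac: 0.20
    asymmetry_ratio: 1.15

plan:
  nx: 10
  ny: 5
  overlap_x: 0.25        # X FOV overlap at 20x
  overlap_y: 0.30        # Y FOV overlap at 20x
  nz: 20                 # planes per Z-stack
  dz_um: 2
  z_start_um: 56

specimen:
  extent_x_um: 900
  extent_y_um: 500
  extent_z_um: 50
  n_filaments: 40
  origin_z_um: 50        # keep the stack away from the Z hard stop

acquisition:
  settle_ms: 350         # wait after motion before exposing
  z_correct: true
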