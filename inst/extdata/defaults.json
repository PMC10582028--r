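{
  "general": {
    "pixel_size": 1.378,
    "seed": 1,
    "gold_bead_diameter_nm": [5],
    "tilt_axis": "y",
    "binning": 8
  },
  "Simulate": {
    "n_tomograms": 2,
    "volume_shape": [200, 200, 100],
    "n_particles": 20,
    "min_dist": 40,
    "border": 24,
    "phantom": "torus",
    "phantom_box": 48,
    "tilt_start": -45,
    "tilt_stop": 45,
    "tilt_increment": 3,
    "ordering": "dose-symmetric",
    "dose_per_tilt": 3,
    "zero_tilt_dose": 0,
    "snr": 0.5,
    "n_beads": 0,
    "voltage_kv": 300,
    "cs_mm": 2.7,
    "amplitude_contrast": 0.07,
    "defocus_um": 3.0
  },
  "SortFiles": {
    "pattern": "{series}_{angle}.mrc"
  },
  "CtfCorrect": {
    "search_min_um": 1.0,
    "search_max_um": 6.0,
    "search_step_um": 0.05,
    "strip_width": 256,
    "handedness": 1
  },
  "Reconstruct": {
    "thickness": 100,
    "filter": "ramp",
    "nad_iterations": 0,
    "nad_kappa": 0.5,
    "nad_dt": 0.1
  },
  "TemplateMatching": {
    "cone_sampling": 20,
    "cone_range": 360,
    "inplane_sampling": 20,
    "inplane_range": 360,
    "symmetry": "C1",
    "chunk": 0,
    "lowpass_A": 0,
    "template_box": 32
  },
  "ExtractParticles": {
    "threshold_sigma": 5,
    "max_particles": 0,
    "exclusion_radius": 0,
    "island_max_size": 0,
    "box": 32,
    "recenter": true,
    "randomize_orientations": false
  },
  "Classify": {
    "n_classes": 3,
    "n_noise_traps": 2,
    "n_iterations": 3,
    "cone_sampling": 15,
    "cone_range": 45,
    "inplane_sampling": 15,
    "inplane_range": 45,
    "shift_limit": 4
  },
  "Average": {
    "symmetry": "C1"
  },
  "Fsc": {
    "threshold": 0.143,
    "split_mode": "even-odd"
  },
  "Cleanup": {
    "stages": ["scratch"],
    "dry_run": false
  },
  "Live": {
    "expected_images_per_series": 31,
    "listen_timeout_s": 30,
    "thickness": 100
  }
}
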