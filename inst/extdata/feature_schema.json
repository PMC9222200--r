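{
  "schema": "babymotion feature registry",
  "scale_note": "Q features are on the percentage scale 0-100 (not fractions).",
  "features": [
    {"name": "Q_med",       "unit": "percent", "description": "median per-frame quantity of motion"},
    {"name": "Q_min",       "unit": "percent", "description": "minimum per-frame quantity of motion"},
    {"name": "Q_max",       "unit": "percent", "description": "maximum per-frame quantity of motion"},
    {"name": "Q_mean",      "unit": "percent", "description": "mean per-frame quantity of motion"},
    {"name": "Q_sd",        "unit": "percent", "description": "sample SD (n-1) of the quantity of motion; movement variability"},
    {"name": "V_my",        "unit": "px/s",    "description": "mean absolute vertical skin-pixel velocity"},
    {"name": "V_mx",        "unit": "px/s",    "description": "mean absolute horizontal skin-pixel velocity"},
    {"name": "V_my_signed", "unit": "px/s",    "description": "mean signed vertical velocity (sensitivity variant; ~0 under symmetric oscillation)"},
    {"name": "V_mx_signed", "unit": "px/s",    "description": "mean signed horizontal velocity (sensitivity variant)"},
    {"name": "A_my",        "unit": "px/s^2",  "description": "mean absolute vertical acceleration of the mean velocity"},
    {"name": "A_mx",        "unit": "px/s^2",  "description": "mean absolute horizontal acceleration of the mean velocity"},
    {"name": "C_sd_x",      "unit": "px",      "description": "SD of the moving-pixel centroid, horizontal"},
    {"name": "C_sd_y",      "unit": "px",      "description": "SD of the moving-pixel centroid, vertical"}
  ],
  "ids": ["n_valid_frames", "video_id", "patient_id"],
  "velocity_units": "pixels per second (no physical calibration; recorded here as metadata)"
}
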