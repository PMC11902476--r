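{
  "rate_hz": 50,
  "seed": 42,
  "spring_coeff": 2.0,
  "noise": {
    "pitch_drift_rate_dps": -0.05,
    "yaw_walk_sd": 0.02,
    "roll_drift_rate_dps": 0,
    "noise_sigma_deg": 0.1
  },
  "keyframes": [
    {"time_s": 0,  "x_mm": 0,    "depth_mm": 40,  "y_mm": 5,   "roll_deg": 1},
    {"time_s": 3,  "x_mm": 120,  "depth_mm": 180, "y_mm": 20,  "roll_deg": -5},
    {"time_s": 6,  "x_mm": -90,  "depth_mm": 10,  "y_mm": -15, "roll_deg": 4},
    {"time_s": 9,  "x_mm": 0,    "depth_mm": 0,   "y_mm": 0,   "roll_deg": 0, "airborne": true},
    {"time_s": 12, "x_mm": 40,   "depth_mm": 220, "y_mm": 10,  "roll_deg": 7},
    {"time_s": 15, "x_mm": 0,    "depth_mm": 60,  "y_mm": 5,   "roll_deg": 0}
  ]
}
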