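{
  "L_shank": 0.45,
  "L_thigh": 0.45,
  "L_torso": 0.60,
  "pelvis_width": 0.28,
  "shoulder_width": 0.38,
  "foot_length": 0.24,
  "heel_back": 0.04,
  "leg_clearance": 0.02,
  "pelvis_drop_max": 0.60,
  "pelvis_backshift_max": 0.18,
  "torso_pitch_max": 30.0,
  "pelvis_yaw_max": 10.0,
  "pelvis_tilt_x_max": 10.0,
  "footYawL": 15.0,
  "footYawR": -15.0,
  "nSteps": 40,
  "profile": "smoothstep",
  "gravity": 9.81,
  "masses": [0, 60, 100, 140]
}
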