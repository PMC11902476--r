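{
  "span_l_mm": 1726,
  "spring_length_mm": 200,
  "sensor_section_end_mm": 200,
  "tape_width_mm": 200,
  "segment_ratio": 0.85,
  "spring_coeff": 2.0,
  "small_angle_deg": 0.1
}
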