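# Default four-quadrant arena rig with a single 10-s LED activation epoch.
# Units: mm, s, mL/min, Hz.
arena:
  radius_mm: 50
  frame_rate_hz: 30
  wind_mode: inward
  arm_flow_ml_min: [100, 100, 100, 100]
  suction_flow_ml_min: 400
  odor_onset_latency_s: 3.5
schedule:
  - kind: LED
    valve_on_s: 10
    duration_s: 10
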