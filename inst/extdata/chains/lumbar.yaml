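# Lumbar segment: trunk relative to pelvis.
# All four rows actuated; theta offsets place the frames so that the neutral
# configuration (all encoders at zero) gives identity orientation.
segment: lumbar
link_lengths:
  r1: 1.0
  r2: 1.0
  r3: 1.0
joint_limits_deg: 90
joints:
  - {a: r1, alpha_deg: 90,  d: 0,     theta_offset_deg: 0,   joint_index: 1, plane: rotation}
  - {a: 0,  alpha_deg: 90,  d: 0,     theta_offset_deg: 90,  joint_index: 2, plane: flexion}
  - {a: 0,  alpha_deg: -90, d: r2+r3, theta_offset_deg: 0,   joint_index: 3, plane: lateral_flexion}
  - {a: 0,  alpha_deg: -90, d: 0,     theta_offset_deg: -90, joint_index: 4, plane: flexion}
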