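# Cervical segment: head relative to trunk.
# Four actuated revolute joints plus one fixed virtual frame whose only role
# is to make the head frame coincide with the trunk frame in the neutral
# pose (all encoders at zero -> identity orientation).
segment: cervical
link_lengths:
  r1: 1.0
  r2: 1.0
  r3: 1.0
joint_limits_deg: 90
joints:
  - {a: r1, alpha_deg: 90,  d: 0,  theta_offset_deg: 0,   joint_index: 1, plane: rotation}
  - {a: r2, alpha_deg: 0,   d: 0,  theta_offset_deg: 0,   joint_index: 2, plane: flexion}
  - {a: 0,  alpha_deg: 90,  d: 0,  theta_offset_deg: 90,  joint_index: 3, plane: flexion}
  - {a: 0,  alpha_deg: -90, d: r3, theta_offset_deg: 0,   joint_index: 4, plane: lateral_flexion}
  - {a: 0,  alpha_deg: -90, d: 0,  theta_offset_deg: -90, joint_index: fixed}
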