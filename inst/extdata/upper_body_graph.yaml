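joint_names:
- spine_base
- neck
- head
- nose
- shoulder_l
- elbow_l
- wrist_l
- shoulder_r
- elbow_r
- wrist_r
center_joint: 1
edges:
- - 1
  - 2
- - 2
  - 3
- - 3
  - 4
- - 2
  - 5
- - 5
  - 6
- - 6
  - 7
- - 2
  - 8
- - 8
  - 9
- - 9
  - 10
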