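# Example SBRT-frame rod geometry (institution-specific hardware; replace
# with your frame's as-built coordinates).  Three silicone rods embedded
# at the bottom of the frame, reference points in frame coordinates (mm).
description: example frame, three rods, V-arrangement
rod_reference_points:
  - [-100.0, 0.0, -150.0]
  - [0.0, 0.0, -170.0]
  - [100.0, 0.0, -150.0]
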