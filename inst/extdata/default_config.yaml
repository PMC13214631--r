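# Default binocular geometry: typical human misalignment angles and the
# resting fixation at the ~1 m abathic distance.
a_cm: 3.25
nodal_cm: 0.6
alpha_deg: 5.2
beta_deg: 3.3
gamma_deg: -2
epsilon_deg: -1
fa_cm: [0, 99.56, 1.72]
convention: gimbal_vertical_first
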