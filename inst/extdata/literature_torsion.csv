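target_position,steps_primary_tertiary_deg,steps_tertiary_tertiary_deg
Nasal up,-4.11,-4.39
Temporal down,-2.38,-2.40
Primary,1.24,0.83
Temporal up,6.38,7.00
Nasal down,3.22,3.50
Primary (repeat),1.03,0.79
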