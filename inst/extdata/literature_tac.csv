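study,horizontal_saccade_tac,vertical_saccade_tac,oblique_displacement_tac
Tweed and Vilis 1990,0.5,NA,NA
Bruno and Van den Berg 1997,0.42,0.28,NA
Crane et al.,0.50,0.45,NA
Thurtell et al. (a),0.57,0.30,NA
Thurtell et al. (b),0.57,0.34,NA
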