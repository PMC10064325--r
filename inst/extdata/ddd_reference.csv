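atc_code,unit_strength_g,ddd_g
J01CA04,1.0,1.5
J01CR02,1.0,1.5
J01CA08,0.2,0.6
J01DC02,0.25,0.5
J01DD13,0.1,0.4
J01DD04,1.0,2.0
J01MA01,0.2,0.4
J01MA02,0.5,1.0
J01FA06,0.15,0.3
J01FA09,0.25,0.5
J01FG01,0.5,2.0
J01XE01,0.05,0.2
J01XX01,3.0,3.0
J01EE01,0.48,1.92
J01AA02,0.1,0.1
M01AE01,0.4,1.2
M01AB05,0.05,0.1
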