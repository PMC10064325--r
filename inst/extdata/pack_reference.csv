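atc_code,units_per_package,units_per_day
J01CA04,14,2
J01CR02,14,2
J01CA08,14,2
J01DC02,14,2
J01DD13,14,2
J01DD04,3,1
J01MA01,10,1
J01MA02,10,2
J01FA06,14,2
J01FA09,14,2
J01FG01,21,3
J01XE01,21,3
J01XX01,1,1
J01EE01,20,2
J01AA02,14,1
M01AE01,20,3
M01AB05,30,3
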