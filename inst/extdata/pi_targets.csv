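indicator_id,direction,optimal_op,optimal_bound,acceptable_op,acceptable_bound
PI1,lower_better,eq,0,lt,0.2
PI2,higher_better,gt,1.5,,
PI3,lower_better,eq,0,lt,10
PI4,lower_better,lt,20,,
PI5,lower_better,lt,20,,
PI6,higher_better,gt,1.5,,
PI7,lower_better,lt,5,lt,20
PI8,lower_better,eq,0,lt,5
PI9,higher_better,ge,90,,
PI10,lower_better,lt,10,lt,30
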