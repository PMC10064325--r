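resident_id,facility_id,event_date,event_type
p2,f1,2019-02-01,urine_culture
p1,f1,2019-05-10,urine_culture
p3,f1,2019-08-01,urine_culture
p2,f1,2019-11-15,urine_culture
p1,f1,2019-10-15,flu_vaccine
p2,f1,2019-11-02,flu_vaccine
p3,f1,2019-01-20,flu_vaccine
p5,f1,2019-10-20,flu_vaccine
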